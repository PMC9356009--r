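#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed configuration. Computed in log
#' space over the parity-matched heterozygote counts.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the test is symmetric in the labelling).
#' @return the exact p-value.
#' @examples
#' hweExact(25, 50, 25)  # modal configuration: p = 1
#' @export
hweExact <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("negative genotype counts")
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one diploid required")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs + 1e-12 * obs])
}

#' SNP quality control
#'
#' Stage \code{"typed"} keeps SNPs with call rate >= 0.95, exact HWE
#' p > 5.9e-7 and MAF > 0.005; stage \code{"imputed"} keeps SNPs with
#' imputation info score >= 0.75 and MAF >= 0.05. Removals are logged with
#' reasons.
#'
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param stage \code{"typed"} or \code{"imputed"}; SNPs of the other stage
#'   pass through untouched.
#' @param thresholds named list overriding the defaults
#'   (call_rate, hwe_p, maf_typed, info, maf_imputed).
#' @return list with \code{genotypes} (filtered) and \code{removed}
#'   (data.frame snp, reason).
#' @export
snpQC <- function(genotypes, stage = c("typed", "imputed"),
                  thresholds = list()) {
  stage <- match.arg(stage)
  th <- utils::modifyList(list(call_rate = 0.95, hwe_p = 5.9e-7,
                               maf_typed = 0.005, info = 0.75,
                               maf_imputed = 0.05), thresholds)
  rd <- rowData(genotypes)
  inStage <- if (stage == "typed") rd$typed else !rd$typed
  reason <- rep(NA_character_, nrow(genotypes))
  if (stage == "typed") {
    reason[inStage & rd$call_rate < th$call_rate] <- "call_rate"
    reason[inStage & is.na(reason) & rd$hwe_p <= th$hwe_p] <- "hwe"
    reason[inStage & is.na(reason) & rd$maf <= th$maf_typed] <- "maf"
  } else {
    reason[inStage & rd$info < th$info] <- "info"
    reason[inStage & is.na(reason) & rd$maf < th$maf_imputed] <- "maf"
  }
  drop <- which(!is.na(reason))
  removed <- data.frame(snp = rownames(genotypes)[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(genotypes)), drop)
  list(genotypes = genotypes[keep, ], removed = removed)
}

#' Kolmogorov-Smirnov normality check for a quantitative trait
#'
#' KS goodness-of-fit of the standardised trait against the standard
#' normal, as a screen for whether a media-normalised response is close
#' enough to Gaussian for the additive score test.
#'
#' @param x trait values (n >= 10 after NA removal).
#' @return the KS p-value.
#' @export
ksNormality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("need at least 10 observations")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate (zero variance) trait")
  suppressWarnings(stats::ks.test((x - mean(x)) / s, "pnorm"))$p.value
}

#' Additive-model score test for a quantitative trait
#'
#' Classical score test of the per-minor-allele effect under the linear
#' model y = a + b g + e: U = sum((g - mean(g)) (y - mean(y))),
#' V = s0^2 sum((g - mean(g))^2) with s0^2 the null (mean-only) maximum
#' likelihood residual variance; the statistic U^2 / V is chi-square with 1
#' df. The reported beta = U / sum((g - mean(g))^2) is the least-squares
#' slope, with SE = sqrt(s0^2 / sum((g - mean(g))^2)). Complete-case: pairs
#' with a missing trait or dosage are dropped (no imputation enters the
#' cQTL analysis).
#'
#' @param trait per-child quantitative values (log2 fold scale).
#' @param dosage per-child minor-allele dosage in [0, 2].
#' @param snp,traitName labels carried into the result.
#' @param minN minimum complete pairs (default 10, the analysis-path rule;
#'   relax only for toy computations).
#' @return one-row data.frame: snp, trait, beta, se, stat, p, n.
#' @export
scoreTestAdditive <- function(trait, dosage, snp = NA_character_,
                              traitName = NA_character_, minN = 10L) {
  ok <- !is.na(trait) & !is.na(dosage)
  y <- trait[ok]; g <- dosage[ok]
  n <- length(y)
  if (n < minN) stop("need at least ", minN, " complete (trait, dosage) pairs")
  sgg <- sum((g - mean(g))^2)
  if (sgg == 0)
    return(data.frame(snp = snp, trait = traitName, beta = NA_real_,
                      se = NA_real_, stat = NA_real_, p = NA_real_, n = n,
                      stringsAsFactors = FALSE))
  U <- sum((g - mean(g)) * (y - mean(y)))
  s0 <- sum((y - mean(y))^2) / n
  V <- s0 * sgg
  stat <- U^2 / V
  data.frame(snp = snp, trait = traitName, beta = U / sgg,
             se = sqrt(s0 / sgg),
             stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
             n = n, stringsAsFactors = FALSE)
}

#' Logistic score test for a binary phenotype
#'
#' Score test under the additive logistic model: with null fitted
#' probability p0 = mean(y), U = sum(g (y - p0)) and
#' V = p0 (1 - p0) sum((g - mean(g))^2); U^2 / V is chi-square with 1 df.
#' A one-step (Fisher scoring from the null) log-odds estimate U / V is
#' reported as beta.
#'
#' @param case per-child logical/0-1 case flags.
#' @param dosage per-child minor-allele dosage in [0, 2].
#' @param snp,traitName labels carried into the result.
#' @param minN minimum complete pairs (default 10).
#' @return one-row data.frame as in \code{\link{scoreTestAdditive}}.
#' @export
scoreTestBinary <- function(case, dosage, snp = NA_character_,
                            traitName = NA_character_, minN = 10L) {
  ok <- !is.na(case) & !is.na(dosage)
  y <- as.numeric(case[ok]); g <- dosage[ok]
  n <- length(y)
  if (n < minN) stop("need at least ", minN, " complete pairs")
  if (length(unique(y)) < 2) stop("both classes must be present")
  p0 <- mean(y)
  sgg <- sum((g - mean(g))^2)
  if (sgg == 0)
    return(data.frame(snp = snp, trait = traitName, beta = NA_real_,
                      se = NA_real_, stat = NA_real_, p = NA_real_, n = n,
                      stringsAsFactors = FALSE))
  U <- sum(g * (y - p0))
  V <- p0 * (1 - p0) * sgg
  stat <- U^2 / V
  data.frame(snp = snp, trait = traitName, beta = U / V, se = sqrt(1 / V),
             stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
             n = n, stringsAsFactors = FALSE)
}

#' Genome-wide cQTL scan over cytokine/stimulus traits
#'
#' Runs the additive score test of every SNP against every requested
#' (cytokine, stimulus) trait on media-normalised, non-imputed fold data,
#' complete-case per trait. Vectorised across SNPs per trait. Results are
#' sorted by p and flagged at the genome-wide threshold.
#'
#' @param folds a \linkS4class{FoldMatrix} (non-imputed).
#' @param genotypes a \linkS4class{GenotypeSet} (QC'd).
#' @param traits data.frame with columns cytokine, stimulus.
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @return data.frame: snp, chrom, pos, trait, beta, se, stat, p, n,
#'   significant.
#' @export
genomeScan <- function(folds, genotypes, traits, threshold = 5e-8) {
  if (!nrow(traits)) stop("empty trait list")
  rd <- rowData(folds)
  G <- t(dosages(genotypes))  # child x snp
  kids <- intersect(colnames(folds), rownames(G))
  G <- G[kids, , drop = FALSE]
  snpInfo <- rowData(genotypes)
  out <- vector("list", nrow(traits))
  for (ti in seq_len(nrow(traits))) {
    row <- which(rd$cytokine == traits$cytokine[ti] &
                   rd$stimulus == traits$stimulus[ti])
    if (!length(row))
      stop("trait not present in fold matrix: ", traits$cytokine[ti], "/",
           traits$stimulus[ti])
    tn <- paste(traits$cytokine[ti], traits$stimulus[ti], sep = ".")
    y <- assay(folds, "log2fold")[row, kids]
    okY <- !is.na(y)
    yv <- y[okY]
    Gt <- G[okY, , drop = FALSE]
    hasNA <- anyNA(Gt)
    if (!hasNA) {
      n <- length(yv)
      gc <- sweep(Gt, 2, colMeans(Gt))
      yc <- yv - mean(yv)
      U <- drop(crossprod(gc, yc))
      sgg <- colSums(gc^2)
      s0 <- sum(yc^2) / n
      stat <- ifelse(sgg > 0, U^2 / (s0 * sgg), NA)
      res <- data.frame(snp = colnames(Gt), trait = tn,
                        beta = ifelse(sgg > 0, U / sgg, NA),
                        se = ifelse(sgg > 0, sqrt(s0 / sgg), NA),
                        stat = stat,
                        p = stats::pchisq(stat, 1, lower.tail = FALSE),
                        n = n, stringsAsFactors = FALSE)
    } else {
      res <- do.call(rbind, lapply(colnames(Gt), function(s)
        scoreTestAdditive(yv, Gt[, s], snp = s, traitName = tn)))
    }
    out[[ti]] <- res
  }
  res <- do.call(rbind, out)
  res$chrom <- snpInfo$chrom[match(res$snp, rownames(snpInfo))]
  res$pos <- snpInfo$pos[match(res$snp, rownames(snpInfo))]
  res <- res[order(res$p), c("snp", "chrom", "pos", "trait", "beta", "se",
                             "stat", "p", "n")]
  res$significant <- !is.na(res$p) & res$p < threshold
  rownames(res) <- NULL
  res
}

#' Specificity profile of a cQTL across predefined pair groups
#'
#' Tests one SNP against every cytokine/stimulus pair in each of the six
#' predefined groups (see \code{\link{defaultSpecificityGroups}}) at
#' nominal significance, reporting per-group pair counts and nominal-hit
#' counts.
#'
#' @param snp SNP id.
#' @param folds a \linkS4class{FoldMatrix}.
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param groups named list of pair data.frames (cytokine, stimulus).
#' @param alpha nominal level (default 0.05, uncorrected).
#' @return list with \code{summary} (group, n_pairs, n_nominal) and
#'   \code{tests} (per-pair results).
#' @export
specificityProfile <- function(snp, folds, genotypes,
                               groups = defaultSpecificityGroups(),
                               alpha = 0.05) {
  if (any(vapply(groups, nrow, integer(1)) == 0)) stop("empty group")
  g <- dosages(genotypes)[snp, ]
  rd <- rowData(folds)
  m <- assay(folds, "log2fold")
  kids <- intersect(colnames(folds), names(g))
  tests <- list()
  for (gn in names(groups)) {
    grp <- groups[[gn]]
    for (i in seq_len(nrow(grp))) {
      row <- which(rd$cytokine == grp$cytokine[i] &
                     rd$stimulus == grp$stimulus[i])
      if (!length(row))
        stop("pair not resolvable: ", grp$cytokine[i], "/", grp$stimulus[i])
      r <- scoreTestAdditive(m[row, kids], g[kids], snp = snp,
                             traitName = paste(grp$cytokine[i],
                                               grp$stimulus[i], sep = "."))
      r$group <- gn
      tests[[length(tests) + 1L]] <- r
    }
  }
  tests <- do.call(rbind, tests)
  agg <- do.call(rbind, lapply(names(groups), function(gn) {
    sub <- tests[tests$group == gn, ]
    data.frame(group = gn, n_pairs = nrow(sub),
               n_nominal = sum(sub$p < alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(summary = agg, tests = tests)
}

#' Phenotype association of cQTLs with clinical outcomes
#'
#' Logistic score tests of each SNP against each binary clinical phenotype.
#'
#' @param snps SNP ids.
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param records clinical data.frame (child_id + logical phenotype
#'   columns).
#' @param phenotypes phenotype column names (default: all logical columns).
#' @return data.frame of score-test results (snp, trait = phenotype, ...).
#' @export
phenotypeAssociation <- function(snps, genotypes, records,
                                 phenotypes = NULL) {
  if (is.null(phenotypes))
    phenotypes <- names(records)[vapply(records, is.logical, logical(1))]
  kids <- intersect(records$child_id, colnames(genotypes))
  res <- list()
  for (s in snps) {
    g <- dosages(genotypes)[s, kids]
    for (ph in phenotypes) {
      y <- records[[ph]][match(kids, records$child_id)]
      res[[length(res) + 1L]] <-
        scoreTestBinary(y, g, snp = s, traitName = ph)
    }
  }
  do.call(rbind, res)
}
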