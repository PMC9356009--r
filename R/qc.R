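#' Floor concentrations at half the lower detection limit
#'
#' Multiplex immunoassay readings below the assay's lower detection limit
#' (LOD) carry no quantitative information; the left-censoring convention
#' records them as half the LOD. Values at or above the LOD, and missing
#' values, pass through unchanged.
#'
#' @param value numeric vector of concentrations (pg/mL), \code{NA} allowed.
#' @param lod lower detection limit(s), > 0 (recycled against \code{value}).
#' @return numeric vector with sub-LOD values replaced by \code{lod / 2}.
#' @examples
#' floorToLOD(c(3, 12, NA), lod = 10)  # 5, 12, NA
#' @export
floorToLOD <- function(value, lod) {
  if (any(lod <= 0)) stop("lod must be > 0")
  ifelse(!is.na(value) & value < lod, lod / 2, value)
}

#' Apply half-LOD flooring to every cell of a CytokineExperiment
#'
#' Uses each cytokine's per-batch LOD, so the same reading can be floored in
#' batch 1 but retained in batch 2.
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @return the floored experiment.
#' @export
floorExperiment <- function(x) {
  b <- childBatch(x)
  for (s in assayNames(x)) {
    a <- assay(x, s)
    for (bt in c("1", "2")) {
      idx <- which(b == bt)
      if (length(idx))
        a[, idx] <- floorToLOD(a[, idx, drop = FALSE], lodOf(x, bt))
    }
    assay(x, s) <- a
  }
  x
}

#' Default sample-level QC thresholds
#'
#' Children are excluded outright below a hard viability floor, and excluded
#' as "inadequate responders" when low viability coincides with absent
#' responses in four sentinel cytokine/stimulus pairs (all criteria must
#' hold simultaneously).
#'
#' @return list with \code{viability_hard} (percent), \code{viability_soft}
#'   (percent) and \code{sentinels}, a data.frame of (cytokine, stimulus,
#'   max_pg_ml) conjunctive criteria.
#' @export
defaultQCThresholds <- function() {
  list(viability_hard = 5, viability_soft = 20,
       sentinels = data.frame(
         cytokine = c("IL2", "IFNa2", "IFNg", "IL6"),
         stimulus = c("PHA", "RSV", "RV16", "Hin"),
         max_pg_ml = c(5, 5, 7, 5),
         stringsAsFactors = FALSE))
}

#' Exclude low-viability and inadequate-responder samples
#'
#' Removes children with viability below the hard threshold, then children
#' meeting ALL of: viability below the soft threshold and every sentinel
#' response below its cutoff. A missing sentinel response cannot demonstrate
#' an absent response, so it fails the conjunction (the child is retained).
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @param thresholds see \code{\link{defaultQCThresholds}}.
#' @param excludeOther named character vector: child id -> free-text reason
#'   for ad-hoc exclusions recorded outside the codified rules.
#' @return list with \code{experiment} (retained children only) and
#'   \code{report}, a list of child-id vectors
#'   (\code{excluded_low_viability}, \code{excluded_inadequate},
#'   \code{excluded_other} with a \code{reason} attribute, \code{retained})
#'   that partitions the input children.
#' @export
applySampleExclusions <- function(x, thresholds = defaultQCThresholds(),
                                  excludeOther = character()) {
  sn <- thresholds$sentinels
  bad <- !sn$cytokine %in% rownames(x) | !sn$stimulus %in% assayNames(x)
  if (any(bad))
    stop("sentinel pair not resolvable: ",
         paste(sn$cytokine[bad], sn$stimulus[bad], sep = "/", collapse = ", "))
  v <- childViability(x)
  ids <- children(x)

  lowV <- ids[v < thresholds$viability_hard]
  rest <- setdiff(ids, lowV)

  sentFail <- rep(TRUE, length(ids))
  names(sentFail) <- ids
  for (i in seq_len(nrow(sn))) {
    r <- responseOf(x, sn$cytokine[i], sn$stimulus[i])
    sentFail <- sentFail & !is.na(r) & r < sn$max_pg_ml[i]
  }
  inad <- rest[v[rest] < thresholds$viability_soft & sentFail[rest]]
  rest <- setdiff(rest, inad)

  other <- intersect(as.character(names(excludeOther)), rest)
  rest <- setdiff(rest, other)
  attr(other, "reason") <- unname(excludeOther[other])

  report <- list(excluded_low_viability = lowV, excluded_inadequate = inad,
                 excluded_other = other, retained = rest)
  list(experiment = x[, rest], report = report)
}

#' Estimate per-pair batch coefficients
#'
#' For every (cytokine, stimulus) pair -- media included, since the assay
#' shift affects control wells too -- regresses the log2 concentration on a
#' batch-1 indicator with batch 2 (the larger batch) as baseline. With a
#' single binary covariate the fitted coefficient equals
#' mean(log2 batch 1) - mean(log2 batch 2); the standard error is the pooled
#' two-sample SE of that difference, identical to the regression SE.
#' Pairs with fewer than 2 observations in either batch get an undefined
#' (NA) coefficient.
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @return data.frame with columns cytokine, stimulus, coefficient, se,
#'   n_batch1, n_batch2 (class \code{"BatchModel"} attribute-free; one row
#'   per pair).
#' @export
estimateBatchModel <- function(x) {
  b <- childBatch(x)
  i1 <- which(b == "1"); i2 <- which(b == "2")
  out <- list()
  for (s in assayNames(x)) {
    l2 <- log2(assay(x, s))
    for (k in rownames(x)) {
      y1 <- l2[k, i1]; y1 <- y1[!is.na(y1)]
      y2 <- l2[k, i2]; y2 <- y2[!is.na(y2)]
      n1 <- length(y1); n2 <- length(y2)
      if (n1 >= 2 && n2 >= 2) {
        coef <- mean(y1) - mean(y2)
        sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) /
          (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      } else {
        coef <- NA_real_; se <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        cytokine = k, stimulus = s, coefficient = coef, se = se,
        n_batch1 = n1, n_batch2 = n2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Subtract batch coefficients from batch-1 responses
#'
#' Batch-1 log2 concentrations have their pair coefficient subtracted;
#' batch-2 values are left bit-identical. Adjusted concentrations that fall
#' below the batch-2 LOD are re-floored to half the batch-2 LOD (the
#' measurement is then effectively below the reference assay's detection
#' limit). Pairs whose coefficient is undefined pass through unadjusted with
#' a warning.
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @param model output of \code{\link{estimateBatchModel}}.
#' @return the adjusted experiment.
#' @export
adjustBatch <- function(x, model) {
  b <- childBatch(x)
  i1 <- which(b == "1")
  und <- model[is.na(model$coefficient) &
                 (model$n_batch1 > 0 | model$n_batch2 > 0), ]
  if (nrow(und))
    warning(nrow(und), " pair(s) observed in fewer than 2 children in a ",
            "batch; passed through unadjusted")
  if (!length(i1)) return(x)
  lod2 <- lodOf(x, "2")
  for (s in assayNames(x)) {
    a <- assay(x, s)
    m <- model[model$stimulus == s, ]
    coef <- m$coefficient[match(rownames(a), m$cytokine)]
    adj <- 2^(log2(a[, i1, drop = FALSE]) - coef)
    keep <- is.na(coef)
    adj[keep, ] <- a[keep, i1, drop = FALSE]
    refloor <- !is.na(adj) & adj < lod2
    adj[refloor] <- (lod2 / 2)[row(adj)[refloor]]
    a[, i1] <- adj
    assay(x, s) <- a
  }
  x
}

#' Media-normalise responses into log2 fold inductions
#'
#' For each child and cytokine, subtracts the log2 media-control
#' concentration from the log2 stimulated concentration. A fold value is
#' missing when either side is missing. The media column is consumed as the
#' reference and does not appear in the result.
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @return a \linkS4class{FoldMatrix} with one row per (cytokine, stimulus)
#'   pair (stimuli in panel rank order).
#' @export
mediaNormalize <- function(x) {
  sp <- stimulusPanel(x)
  med <- mediaName(sp)
  l2m <- log2(assay(x, med))
  stim <- setdiff(sp$stimulus[order(sp$rank)], med)
  blocks <- lapply(stim, function(s) log2(assay(x, s)) - l2m)
  vals <- do.call(rbind, blocks)
  info <- data.frame(cytokine = rep(rownames(x), length(stim)),
                     stimulus = rep(stim, each = nrow(x)),
                     stringsAsFactors = FALSE)
  rownames(vals) <- paste(info$cytokine, info$stimulus, sep = ".")
  FoldMatrix(vals, info, sp, cytokinePanel(x))
}

#' Bonferroni-corrected significance level for induction testing
#'
#' One test is run per cytokine/stimulus pair, so the family-wise level 0.05
#' is divided by the number of pairs; for a 28-cytokine, 15-stimulus panel
#' this gives 0.05/420, approximately 1.19e-4.
#'
#' @param nCytokines,nStimuli positive integers.
#' @return the per-test significance level.
#' @examples
#' bonferroniAlpha(28, 15)
#' @export
bonferroniAlpha <- function(nCytokines, nStimuli) {
  if (nCytokines < 1 || nStimuli < 1) stop("counts must be >= 1")
  0.05 / (nCytokines * nStimuli)
}

#' Test each pair for significant induction over media
#'
#' One-sample, right one-sided t-test per (cytokine, stimulus) pair of the
#' null that the mean log2 fold induction is zero, against mean > 0. The
#' mean fold induction is reported back-transformed (2^mean log2 fold, a
#' geometric mean). Pairs with fewer than 2 observations or zero variance
#' are flagged untestable rather than significant.
#'
#' @param folds a \linkS4class{FoldMatrix} (or plain child-row matrix).
#' @param alpha per-test significance level, e.g.
#'   \code{bonferroniAlpha(28, 15)}.
#' @return data.frame: pair, cytokine, stimulus, n, mean_log2_fold,
#'   mean_fold, t, p, significant, untestable.
#' @export
testInduction <- function(folds, alpha = bonferroniAlpha(28, 15)) {
  m <- if (is(folds, "FoldMatrix")) foldValues(folds) else folds
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sd <- apply(m, 2, stats::sd, na.rm = TRUE)
  t <- mu / (sd / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  untestable <- n < 2 | (!is.na(sd) & sd == 0)
  t[untestable] <- NA; p[untestable] <- NA
  res <- data.frame(pair = colnames(m), n = n, mean_log2_fold = mu,
                    mean_fold = 2^mu, t = t, p = p,
                    significant = !untestable & p < alpha,
                    untestable = untestable, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (is(folds, "FoldMatrix")) {
    rd <- rowData(folds)
    res <- cbind(res[1], cytokine = rd$cytokine, stimulus = rd$stimulus,
                 res[-1])
  }
  res
}

#' Viability diagnostics
#'
#' Checks whether viability is predicted by batch assignment (linear
#' regression F/p) and whether each (cytokine, stimulus) response is
#' associated with viability (Pearson r with its t-transform p).
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @return list with \code{batch_p} and data.frame \code{response_viability}
#'   (cytokine, stimulus, r, p, n).
#' @export
viabilityDiagnostics <- function(x) {
  if (ncol(x) < 3) stop("need at least 3 children")
  v <- childViability(x)
  fit <- stats::lm(v ~ factor(childBatch(x)))
  bp <- stats::anova(fit)[["Pr(>F)"]][1]
  out <- list()
  for (s in assayNames(x)) {
    conc <- assay(x, s)
    for (k in rownames(x)) {
      y <- conc[k, ]
      ok <- !is.na(y)
      n <- sum(ok)
      if (n >= 3 && stats::sd(y[ok]) > 0 && stats::sd(v[ok]) > 0) {
        ct <- stats::cor.test(y[ok], v[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        cytokine = k, stimulus = s, r = r, p = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  list(batch_p = bp, response_viability = do.call(rbind, out))
}
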