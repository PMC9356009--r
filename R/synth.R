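#' Signature model for the synthetic cohort generator
#'
#' Bundles the generating parameters of a synthetic PBMC cytokine study:
#' per-cytokine media baselines, the (cytokine, stimulus) mean log2
#' fold-induction signature, per-functional-group child reactivity SDs
#' (one scalar multiplier per group per child, which produces both the
#' >1000-fold between-child ranges and the strong within-group pair
#' correlations), an additive log2 batch-1 shift, residual noise, additive
#' genetic effects and phenotype links.
#'
#' @param media_baseline named numeric, per-cytokine mean log2 concentration
#'   of the media well.
#' @param signature cytokine x stimulus matrix of mean log2 fold-induction
#'   effects; must be 0 in the media column.
#' @param child_reactivity_sd named numeric, SD of the child-level log2
#'   multiplier per functional group (>= 0).
#' @param batch_shift cytokine x stimulus matrix of additive log2 offsets
#'   applied to batch-1 measurements (media included: the shift is an assay
#'   property).
#' @param noise_sd residual log2 SD (>= 0).
#' @param genetic_effects data.frame: snp, cytokine, stimuli
#'   (comma-separated stimulus set), beta (per-minor-allele log2 effect),
#'   maf.
#' @param phenotype_links data.frame: snp, phenotype, log_odds per allele;
#'   every snp must appear in \code{genetic_effects}.
#' @param inadequate_rate fraction of children simulated as anergic
#'   "inadequate responders" (no induction, depressed absolute levels, low
#'   viability).
#' @param low_viability_rate fraction of children with viability below the
#'   hard QC floor.
#' @param phenotype_prevalence baseline prevalence of the binary clinical
#'   phenotypes in non-carriers.
#' @return a list of class \code{"SignatureModel"}.
#' @export
signatureModel <- function(media_baseline, signature, child_reactivity_sd,
                           batch_shift, noise_sd, genetic_effects,
                           phenotype_links, inadequate_rate = 0,
                           low_viability_rate = 0,
                           phenotype_prevalence = 0.18) {
  stopifnot(all(child_reactivity_sd >= 0), noise_sd >= 0)
  if (nrow(phenotype_links) &&
      !all(phenotype_links$snp %in% genetic_effects$snp))
    stop("phenotype link references unknown SNP")
  structure(list(media_baseline = media_baseline, signature = signature,
                 child_reactivity_sd = child_reactivity_sd,
                 batch_shift = batch_shift, noise_sd = noise_sd,
                 genetic_effects = genetic_effects,
                 phenotype_links = phenotype_links,
                 inadequate_rate = inadequate_rate,
                 low_viability_rate = low_viability_rate,
                 phenotype_prevalence = phenotype_prevalence),
            class = "SignatureModel")
}

#' Default generating model
#'
#' Encodes, as generating truth, the headline statistics of a two-batch,
#' 28-cytokine x 15-stimulus childhood cohort: strong viral induction of
#' IFN-a2/IP-10/IFN-g, strong bacterial induction of IL-6 (geometric-mean
#' fold 280 for the strongest bacterial stimulus) and the other
#' pro-inflammatory cytokines, PHA induction of T-cell cytokines (IL-17
#' geometric-mean fold 67), child reactivity SDs giving >1000-fold
#' between-child ranges, a -0.7 log2 batch-1 shift, and a residual SD
#' calibrated so the child-level IL-6 LPS~Hin correlation is 0.95. Six
#' cQTLs act on IL-6/bacterial responses at published effect scales; the
#' signature is stated net of the mean genetic contribution so cohort-level
#' geometric-mean folds equal their targets.
#'
#' @param stimulusPanel,cytokinePanel panels (defaults used when omitted).
#' @return a \code{"SignatureModel"}.
#' @export
defaultSignatureModel <- function(stimulusPanel = defaultStimulusPanel(),
                                  cytokinePanel = defaultCytokinePanel()) {
  sp <- stimulusPanel; cp <- cytokinePanel
  cyt <- cp$cytokine; stim <- sp$stimulus
  grp <- stats::setNames(cp$functional_group, cyt)
  sgrp <- stats::setNames(sp$group, stim)
  viral <- stim[sgrp == "viral"]; bact <- stim[sgrp == "bacterial"]
  med <- mediaName(sp)

  base_by_group <- c(anti_viral = 3, pro_inflammatory = 3.3, t_cell = 2,
                     weak = 1.6)
  media_baseline <- base_by_group[grp]
  names(media_baseline) <- cyt

  d <- matrix(0, length(cyt), length(stim), dimnames = list(cyt, stim))
  set1 <- function(k, v) d[k, names(v)] <<- v
  d[, setdiff(stim, med)] <- 0.3  # weak background induction
  set1("IFNa2", c(RV16 = 10, RSV = 10, RV1B = 8, polyIC = 6, R848 = 10,
                  CpGA = 10, PHA = 1))
  d["IFNa2", bact] <- 1
  set1("IP10", c(RV16 = 8, RSV = 8, RV1B = 8, polyIC = 5, R848 = 8,
                 CpGA = 7, PHA = 4))
  d["IP10", bact] <- 3
  d["MCP1", viral] <- 3
  set1("MCP1", c(R848 = 2.5, PAM = 2.5, FSL = 2.5, PHA = 2))
  d["eotaxin1", viral] <- 2
  set1("MCP4", c(RV16 = 3, RV1B = 3, RSV = 2.5, CpGA = 2, R848 = 2,
                 polyIC = 1.5, PHA = 0.5))
  d["IL1b", bact] <- 4.5
  set1("IL1b", c(R848 = 4, PHA = 3, RSV = 0.3))
  set1("IL6", c(Hin = log2(280), LPS = 7.8, Strpn = 7.3, PGN = 7.0,
                Fla = 6.8, LTA = 6.6, PAM = 6.4, FSL = 6.2, R848 = 6,
                RSV = log2(38), RV16 = 3, RV1B = 3, CpGA = 1, polyIC = 4.5,
                PHA = 3.3))
  d["IL8", bact] <- 4
  set1("IL8", c(R848 = 3.5, PHA = 3, RSV = 0.3))
  d["MIP1b", bact] <- 5
  set1("MIP1b", c(R848 = 4.5, RSV = 2.3, RV16 = 1.5, RV1B = 1.5, PHA = 3))
  d["TNF", bact] <- 4.8
  set1("TNF", c(R848 = 4, RSV = 1, RV16 = 1, RV1B = 1, PHA = 3))
  d["IL10", bact] <- 4.5
  d["IL10", viral] <- 1.5
  set1("IL10", c(PHA = 3))
  d["MDC", bact] <- 2
  d["MDC", viral] <- 1
  set1("MDC", c(PHA = 2))
  set1("IL17", c(PHA = log2(67), PGN = 2.5))
  d["IL17", setdiff(bact, "PGN")] <- 0.5
  d["IFNg", viral] <- c(RV16 = 8, RSV = 8, RV1B = 7, polyIC = 5, R848 = 8,
                        CpGA = 7)[viral]
  set1("IFNg", c(Hin = 8, LPS = 7.5, Strpn = 1.5, PAM = 1.5, FSL = 1.5,
                 PGN = 3, Fla = 3, LTA = 3, PHA = 8.2))
  set1("IL2", c(PHA = 6))
  set1("IL4", c(PHA = 4))
  set1("IL5", c(PHA = 6))
  set1("IL13", c(PHA = 6.5))
  set1("IL12p70", c(PHA = 2.5))
  d["IL12p70", bact] <- 1
  d[, med] <- 0

  ge <- data.frame(
    snp = c("rs_il6_a", "rs_il6_b", "rs_il6_c", "rs_il6_d", "rs_il6_e",
            "rs_il6_f",
            "rs_av_a", "rs_av_b", "rs_av_c", "rs_av_d", "rs_av_e",
            "rs_tc_a", "rs_tc_b", "rs_tc_c",
            "rs_ifng_a", "rs_ifng_b", "rs_ifng_c",
            "rs_tnf_a", "rs_tnf_b", "rs_tnf_c"),
    cytokine = c(rep("IL6", 6), rep("IFNa2", 5), rep("IL17", 3),
                 rep("IFNg", 3), rep("TNF", 3)),
    stimuli = c(rep(paste(bact, collapse = ","), 6),
                rep("RSV,RV16,R848,CpGA", 5), rep("PHA", 3),
                rep("Hin,LPS", 3), rep(paste(bact, collapse = ","), 3)),
    beta = c(-1.50, -1.26, -1.36, -1.56, -1.64, -1.88,
             -1.40, -1.20, 1.10, -0.90, 0.80,
             -0.80, 0.90, -1.00,
             -1.00, 0.90, -0.70,
             -0.80, 0.70, -0.60),
    maf = c(rep(0.10, 6), rep(0.20, 5), rep(0.20, 3), rep(0.25, 3),
            rep(0.30, 3)),
    stringsAsFactors = FALSE)

  # state the signature net of the mean genetic contribution so that the
  # cohort-level geometric-mean folds hit their targets
  for (i in seq_len(nrow(ge))) {
    ss <- strsplit(ge$stimuli[i], ",")[[1]]
    d[ge$cytokine[i], ss] <- d[ge$cytokine[i], ss] - ge$beta[i] * 2 * ge$maf[i]
  }

  pl <- data.frame(
    snp = c("rs_il6_e", "rs_il6_f", "rs_il6_f"),
    phenotype = c("unscheduled_asthma_visit", "oral_steroid_receipt",
                  "gina_step2"),
    log_odds = c(0.32, 0.57, 0.73), stringsAsFactors = FALSE)

  shift <- matrix(-0.7, length(cyt), length(stim),
                  dimnames = list(cyt, stim))

  signatureModel(
    media_baseline = media_baseline, signature = d,
    child_reactivity_sd = c(anti_viral = 2.8, pro_inflammatory = 2.0,
                            t_cell = 1.5, weak = 0.5),
    batch_shift = shift, noise_sd = 0.605,
    genetic_effects = ge, phenotype_links = pl,
    inadequate_rate = 0.056, low_viability_rate = 0.038,
    phenotype_prevalence = 0.18)
}

#' Simulation configuration
#'
#' @param n_children total cohort size (default 340, trimmed towards ~307 by
#'   the QC stage).
#' @param batch_sizes two positive integers summing to \code{n_children}
#'   (default 54 + 286).
#' @param seed integer; fixes every stochastic draw.
#' @param stimulusPanel,cytokinePanel panels.
#' @param model a \code{"SignatureModel"}.
#' @param n_null_snps number of non-causal SNPs to simulate.
#' @param apply_missingness draw per-child available-stimulus counts and
#'   mask responses (default TRUE).
#' @return list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_children = 340L, batch_sizes = c(54L, 286L),
                      seed = 1L, stimulusPanel = defaultStimulusPanel(),
                      cytokinePanel = defaultCytokinePanel(),
                      model = defaultSignatureModel(stimulusPanel,
                                                    cytokinePanel),
                      n_null_snps = 2000L, apply_missingness = TRUE) {
  if (n_children <= 0) stop("n_children must be positive")
  if (length(batch_sizes) != 2L || any(batch_sizes <= 0))
    stop("batch_sizes must be two positive integers")
  if (sum(batch_sizes) != n_children)
    stop("batch sizes must sum to n_children")
  validateStimulusPanel(stimulusPanel)
  validateCytokinePanel(cytokinePanel)
  structure(list(n_children = as.integer(n_children),
                 batch_sizes = as.integer(batch_sizes),
                 seed = as.integer(seed), stimulusPanel = stimulusPanel,
                 cytokinePanel = cytokinePanel, model = model,
                 n_null_snps = as.integer(n_null_snps),
                 apply_missingness = isTRUE(apply_missingness)),
            class = "SimConfig")
}

#' Draw per-child available-stimulus counts matching panel missing rates
#'
#' Under the monotone culture-order mechanism a child with available count K
#' is missing exactly the stimuli of rank > K, so
#' P(missing rank r) = P(K < r). The count distribution solving these
#' marginal constraints is P(K = 0) = t_1, P(K = r) = t_(r+1) - t_r,
#' P(K = n) = 1 - t_n, where t_r is the target rate of the rank-r stimulus.
#'
#' @param n number of children.
#' @param panel stimulus panel.
#' @return integer vector of counts in [0, n_stimuli].
#' @export
drawStimulusCounts <- function(n, panel) {
  t <- panel$target_missing_rate[order(panel$rank)]
  ns <- length(t)
  p <- c(t[1], diff(t), 1 - t[ns])
  sample(0:ns, n, replace = TRUE, prob = p)
}

#' Mask responses by culture rank
#'
#' For each child, stimuli whose rank exceeds the child's available count
#' are set fully missing (all cytokines); the mask is therefore monotone in
#' rank, and the media control (rank 1) is retained whenever at least one
#' condition was cultured.
#'
#' @param x a \linkS4class{CytokineExperiment}.
#' @param counts per-child available-stimulus counts.
#' @param panel stimulus panel (defaults to the experiment's).
#' @return the masked experiment.
#' @export
applyRankMissingness <- function(x, counts, panel = stimulusPanel(x)) {
  ns <- nrow(panel)
  if (any(counts < 0 | counts > ns))
    stop("counts must lie in [0, ", ns, "]")
  rk <- stats::setNames(panel$rank, panel$stimulus)
  for (s in assayNames(x)) {
    a <- assay(x, s)
    a[, counts < rk[s]] <- NA_real_
    assay(x, s) <- a
  }
  x
}

#' Generate synthetic genotypes in Hardy-Weinberg proportions
#'
#' Causal SNPs (from the model's genetic effects) are generated at their
#' configured MAFs as genotyped markers; null SNPs get MAFs uniform on
#' [0.05, 0.5], a fraction are flagged imputed with sub-unity info scores,
#' and a small fraction get depressed call rates with missing calls, so the
#' QC filters have work to do.
#'
#' @param childIds character vector.
#' @param effects genetic-effects data.frame (snp, beta, maf, ...).
#' @param nNull number of null SNPs.
#' @return a \linkS4class{GenotypeSet}.
#' @export
generateGenotypes <- function(childIds, effects, nNull = 2000L) {
  n <- length(childIds)
  ids <- c(effects$snp, sprintf("rs_null_%04d", seq_len(nNull)))
  maf <- c(effects$maf, stats::runif(nNull, 0.05, 0.5))
  m <- length(ids)
  if (m == 0L)
    return(GenotypeSet(
      matrix(numeric(0), 0, n, dimnames = list(character(0), childIds)),
      data.frame(chrom = integer(0), pos = numeric(0), ref = character(0),
                 alt = character(0), typed = logical(0),
                 call_rate = numeric(0), info = numeric(0), maf = numeric(0),
                 hwe_p = numeric(0))))
  dos <- matrix(stats::rbinom(m * n, 2L, rep(maf, n)), nrow = m, ncol = n,
                dimnames = list(ids, childIds))
  typed <- c(rep(TRUE, nrow(effects)),
             stats::runif(nNull) > 0.3)
  info <- ifelse(typed, 1, stats::runif(m, 0.5, 1))
  lowcall <- !typed & stats::runif(m) < 0.02 / 0.3
  lowcall <- lowcall | (seq_len(m) > nrow(effects) & stats::runif(m) < 0.02)
  for (i in which(lowcall)) {
    miss <- stats::runif(1, 0.05, 0.10)
    dos[i, stats::runif(n) < miss] <- NA
  }
  call_rate <- rowMeans(!is.na(dos))
  emp_maf <- pmin(rowMeans(dos, na.rm = TRUE) / 2,
                  1 - rowMeans(dos, na.rm = TRUE) / 2)
  hwe_p <- apply(dos, 1, function(g) {
    g <- g[!is.na(g)]
    hweExact(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  info_snp <- data.frame(
    chrom = sample(1:22, m, replace = TRUE),
    pos = sort(sample.int(2.5e8, m)),
    ref = "A", alt = "G", typed = typed, call_rate = call_rate,
    info = info, maf = emp_maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
  GenotypeSet(dos, info_snp)
}

#' Classify a year's medication set into a GINA treatment step
#'
#' Applies the stepwise rules: step 5 for oral corticosteroids or anti-IgE;
#' step 4 for medium/high-dose ICS plus LABA or a leukotriene modifier;
#' step 3 for low-dose ICS plus LABA/LTRA/sustained-release theophylline,
#' medium/high-dose ICS alone, or a combination inhaler; step 2 for low-dose
#' ICS or LTRA alone; otherwise step 1 (as-needed SABA with no controller).
#' Adding a medication can never lower the step.
#'
#' @param classes character vector of drug classes received that year
#'   (subset of SABA, ipratropium, cromoglicate, LABA, ICS_low,
#'   ICS_medium_high, combination, LTRA, theophylline_SR, OCS, anti_IgE).
#' @return integer step in 1..5.
#' @examples
#' deriveGinaStep(c("SABA"))                    # 1
#' deriveGinaStep(c("SABA", "ICS_low"))         # 2
#' deriveGinaStep(c("ICS_medium_high", "LABA")) # 4
#' @export
deriveGinaStep <- function(classes) {
  known <- c("SABA", "ipratropium", "cromoglicate", "LABA", "ICS_low",
             "ICS_medium_high", "combination", "LTRA", "theophylline_SR",
             "OCS", "anti_IgE")
  bad <- setdiff(classes, known)
  if (length(bad)) stop("unknown drug class: ", paste(bad, collapse = ", "))
  has <- function(x) any(x %in% classes)
  if (has(c("OCS", "anti_IgE"))) return(5L)
  if (has("ICS_medium_high") && has(c("LABA", "LTRA"))) return(4L)
  if ((has("ICS_low") && has(c("LABA", "LTRA", "theophylline_SR"))) ||
      has("ICS_medium_high") || has("combination")) return(3L)
  if (has(c("ICS_low", "LTRA"))) return(2L)
  1L
}

#' @rdname deriveGinaStep
#' @param medications data.frame (child_id, age_days, drug_class).
#' @param childId child identifier.
#' @param year follow-up year (year y covers ages [365(y-1), 365y) days).
#' @export
deriveGinaStepYear <- function(medications, childId, year) {
  sel <- medications$child_id == childId &
    medications$age_days >= 365 * (year - 1) &
    medications$age_days < 365 * year
  deriveGinaStep(unique(medications$drug_class[sel]))
}

medsForStep <- function(step) {
  switch(step,
         `1` = "SABA",
         `2` = c("SABA", "ICS_low"),
         `3` = c("SABA", "ICS_low", "LABA"),
         `4` = c("SABA", "ICS_medium_high", "LABA"),
         `5` = c("SABA", "ICS_medium_high", "LABA", "OCS"))
}

generateClinical <- function(childIds, geno, model) {
  n <- length(childIds)
  prev <- model$phenotype_prevalence
  dos <- dosages(geno)
  logit0 <- stats::qlogis(prev)
  phen <- c("unscheduled_asthma_visit", "oral_steroid_receipt",
            "gina_step2", "admission_after_age3")
  rec <- data.frame(child_id = childIds, stringsAsFactors = FALSE)
  for (ph in phen) {
    eta <- rep(logit0, n)
    pl <- model$phenotype_links[model$phenotype_links$phenotype == ph, ]
    for (i in seq_len(nrow(pl)))
      eta <- eta + pl$log_odds[i] * dos[pl$snp[i], childIds]
    rec[[ph]] <- stats::runif(n) < stats::plogis(eta)
  }
  # medication histories consistent with the GINA case/control status at
  # year 8 (cases: controller therapy; controls: at most as-needed SABA)
  meds <- list()
  steps <- integer(n)
  for (i in seq_len(n)) {
    if (rec$gina_step2[i]) {
      step <- sample(2:5, 1, prob = c(0.60, 0.25, 0.10, 0.05))
    } else {
      step <- 1L
      if (stats::runif(1) > 0.45) next  # no asthma medication at all
    }
    steps[i] <- step
    cls <- medsForStep(step)
    meds[[length(meds) + 1L]] <- data.frame(
      child_id = childIds[i],
      age_days = sample(2555:2919, length(cls), replace = TRUE),
      drug_class = cls, stringsAsFactors = FALSE)
  }
  meds <- if (length(meds)) do.call(rbind, meds) else
    data.frame(child_id = character(), age_days = numeric(),
               drug_class = character())
  list(records = rec, medications = meds)
}

#' Generate a full synthetic cohort
#'
#' Draws, in a fixed order under the configured seed: viability categories
#' and values, per-child functional-group reactivities, genotypes, clinical
#' phenotypes and medication histories, cytokine responses, left-censoring,
#' and the rank-monotone missingness mask. The log2 concentration of child
#' c, cytokine k, stimulus s is
#' \code{baseline(k) + delta(k,s) + a[c, group(k)] * (s != media) +
#' shift(k,s) * (batch(c) == 1) + sum(beta * dosage(c)) + eps}, with
#' \code{eps ~ N(0, noise_sd^2)}; concentrations below the batch LOD are
#' stored as half the LOD.
#'
#' @param config a \code{"SimConfig"}.
#' @return list with \code{experiment} (\linkS4class{CytokineExperiment}),
#'   \code{genotypes} (\linkS4class{GenotypeSet}), \code{clinical} (records
#'   + medications data.frames), \code{counts} (per-child available-stimulus
#'   counts) and \code{truth} (the generating \code{"SignatureModel"}).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  m <- config$model
  sp <- config$stimulusPanel; cp <- config$cytokinePanel
  n <- config$n_children
  cyt <- cp$cytokine; stim <- sp$stimulus
  med <- mediaName(sp)
  ids <- sprintf("child_%03d", seq_len(n))
  batch <- rep(c("1", "2"), config$batch_sizes)

  u <- stats::runif(n)
  lowv <- u < m$low_viability_rate
  inad <- !lowv & u < m$low_viability_rate + m$inadequate_rate
  viability <- 100 * stats::rbeta(n, 8, 1.5)
  viability[inad] <- stats::runif(sum(inad), 5, 19.9)
  viability[lowv] <- stats::runif(sum(lowv), 0, 4.9)

  grps <- c("anti_viral", "pro_inflammatory", "t_cell", "weak")
  a <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(ids, grps))
  a <- sweep(a, 2, m$child_reactivity_sd[grps], `*`)
  a[inad, ] <- 0

  geno <- generateGenotypes(ids, m$genetic_effects, config$n_null_snps)
  clinical <- generateClinical(ids, geno, m)

  gshift <- matrix(0, length(cyt), n, dimnames = list(cyt, ids))
  gBystim <- lapply(stats::setNames(stim, stim), function(s) gshift)
  dos <- dosages(geno)
  for (i in seq_len(nrow(m$genetic_effects))) {
    ge <- m$genetic_effects[i, ]
    ss <- strsplit(ge$stimuli, ",")[[1]]
    g <- dos[ge$snp, ids]
    g[is.na(g)] <- 2 * ge$maf
    for (s in ss)
      gBystim[[s]][ge$cytokine, ] <- gBystim[[s]][ge$cytokine, ] + ge$beta * g
  }

  grpOf <- stats::setNames(cp$functional_group, cyt)
  aK <- t(a)[grpOf, , drop = FALSE]  # cytokine x child reactivity
  rownames(aK) <- cyt
  assaysL <- list()
  for (s in stim) {
    mu <- m$media_baseline[cyt] + m$signature[cyt, s]
    l2 <- matrix(mu, length(cyt), n) +
      matrix(stats::rnorm(length(cyt) * n, sd = m$noise_sd), length(cyt), n)
    if (s != med) l2 <- l2 + aK + gBystim[[s]]
    if (any(inad))  # anergic responders: no induction, depressed levels
      l2[, inad] <- m$media_baseline[cyt] - 4 +
        matrix(stats::rnorm(length(cyt) * sum(inad), sd = m$noise_sd),
               length(cyt), sum(inad))
    l2 <- l2 + m$batch_shift[cyt, s] * rep(batch == "1", each = length(cyt))
    conc <- 2^l2
    for (bt in c("1", "2")) {
      idx <- which(batch == bt)
      lod <- cp[[paste0("lod_batch", bt)]]
      sub <- conc[, idx, drop = FALSE]
      low <- sub < lod
      sub[low] <- (lod / 2)[row(sub)[low]]
      conc[, idx] <- sub
    }
    dimnames(conc) <- list(cyt, ids)
    assaysL[[s]] <- conc
  }

  x <- CytokineExperiment(assaysL, batch, viability, sp, cp)
  counts <- rep(nrow(sp), n)
  if (config$apply_missingness) {
    counts <- drawStimulusCounts(n, sp)
    x <- applyRankMissingness(x, counts, sp)
  }
  list(experiment = x, genotypes = geno, clinical = clinical,
       counts = counts, truth = m)
}
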