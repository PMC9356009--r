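#' Pipeline configuration
#'
#' Settings for the end-to-end analysis. Per-stage seeds are derived from
#' the master seed by a fixed counter scheme (seed + 100 * stage index), so
#' any stage can be re-run in isolation reproducibly.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param sim a \code{"SimConfig"} to simulate inputs, or NULL when reading
#'   from files.
#' @param cytokine_table,vcf,clinical_table input paths (used when
#'   \code{sim} is NULL).
#' @param qc_thresholds see \code{\link{defaultQCThresholds}}.
#' @param stimulus_exclusions stimuli excluded from clustering/PCA
#'   (default polyIC).
#' @param k_candidates PPCA dimensionality candidates.
#' @param n_boot,scales multiscale bootstrap settings.
#' @param cqtl_threshold genome-wide significance threshold.
#' @param cqtl_traits data.frame (cytokine, stimulus) of scan traits;
#'   default IL-6 against the eight bacterial stimuli.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outdir, seed = 1L, sim = NULL,
                           cytokine_table = NULL, vcf = NULL,
                           clinical_table = NULL,
                           qc_thresholds = defaultQCThresholds(),
                           stimulus_exclusions = "polyIC",
                           k_candidates = 1:10,
                           n_boot = 1000L,
                           scales = seq(0.5, 1.4, by = 0.1),
                           cqtl_threshold = 5e-8,
                           cqtl_traits = NULL) {
  if (is.null(cqtl_traits))
    cqtl_traits <- data.frame(
      cytokine = "IL6",
      stimulus = c("Hin", "Strpn", "LPS", "PAM", "PGN", "FSL", "Fla", "LTA"),
      stringsAsFactors = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 cytokine_table = cytokine_table, vcf = vcf,
                 clinical_table = clinical_table,
                 qc_thresholds = qc_thresholds,
                 stimulus_exclusions = stimulus_exclusions,
                 k_candidates = k_candidates, n_boot = as.integer(n_boot),
                 scales = scales, cqtl_threshold = cqtl_threshold,
                 cqtl_traits = cqtl_traits),
            class = "PipelineConfig")
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "outdir")], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: half-LOD flooring, sample exclusions, batch
#' coefficient estimation and subtraction, media normalisation, induction
#' testing, PPCA imputation (clustering path only), tensor unfoldings with
#' PCA, multiscale-bootstrap clustering of stimuli and cytokines, the cQTL
#' genome scan on non-imputed folds, specificity profiling of the top SNP,
#' and phenotype association of genome-wide significant SNPs. All artifacts
#' are written under \code{outdir}; the run is deterministic given the
#' seed.
#'
#' @param config a \code{"PipelineConfig"}.
#' @return the run manifest (also written as manifest.json): config hash,
#'   seed, per-stage timings, input counts, exclusion log, and one entry
#'   per output artifact.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  timings <- c()
  artifacts <- character()
  tic <- function() proc.time()[["elapsed"]]
  stageSeed <- function(i) config$seed + 100L * i

  t0 <- tic()
  if (!is.null(config$sim)) {
    cohort <- generateCohort(config$sim)
    x <- cohort$experiment
    geno <- cohort$genotypes
    clinical <- cohort$clinical$records
    writeSignatureModel(cohort$truth, out("truth.yaml"))
    artifacts <- c(artifacts, "truth.yaml")
  } else {
    x <- readCytokineTable(config$cytokine_table)
    geno <- if (!is.null(config$vcf)) readGenotypes(config$vcf) else NULL
    clinical <- if (!is.null(config$clinical_table))
      utils::read.delim(config$clinical_table,
                        colClasses = c(child_id = "character")) else NULL
    if (!is.null(clinical))
      for (ph in setdiff(names(clinical), "child_id"))
        clinical[[ph]] <- as.logical(clinical[[ph]])
  }
  nInput <- ncol(x)
  timings["input"] <- tic() - t0

  # QC: flooring + exclusions + batch adjustment
  t0 <- tic()
  x <- floorExperiment(x)
  qc <- applySampleExclusions(x, config$qc_thresholds)
  x <- qc$experiment
  qrep <- qc$report
  qcTab <- data.frame(
    child_id = c(qrep$excluded_low_viability, qrep$excluded_inadequate,
                 qrep$excluded_other, qrep$retained),
    status = c(rep("excluded_low_viability", length(qrep$excluded_low_viability)),
               rep("excluded_inadequate", length(qrep$excluded_inadequate)),
               rep("excluded_other", length(qrep$excluded_other)),
               rep("retained", length(qrep$retained))),
    stringsAsFactors = FALSE)
  utils::write.table(qcTab, out("qc_report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bm <- estimateBatchModel(x)
  utils::write.table(bm, out("batch_model.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  x <- adjustBatch(x, bm)
  artifacts <- c(artifacts, "qc_report.tsv", "batch_model.tsv")
  timings["qc"] <- tic() - t0

  # media normalisation + induction testing
  t0 <- tic()
  folds <- mediaNormalize(x)
  alpha <- bonferroniAlpha(nrow(x), length(assayNames(x)) - 1L)
  ind <- testInduction(folds, alpha)
  utils::write.table(ind, out("induction_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeFoldTable(folds, out("fold_matrix.tsv"))
  artifacts <- c(artifacts, "induction_tests.tsv", "fold_matrix.tsv")
  timings["normalize"] <- tic() - t0

  # imputation (clustering path only)
  t0 <- tic()
  imp <- imputeFolds(folds, kCandidates = config$k_candidates,
                     seed = stageSeed(1L))
  writeFoldTable(imp$folds, out("fold_matrix_imputed.tsv"))
  artifacts <- c(artifacts, "fold_matrix_imputed.tsv")
  timings["impute"] <- tic() - t0

  # unfoldings + PCA
  t0 <- tic()
  vStim <- unfold(imp$folds, "child_cytokine_by_stimulus",
                  config$stimulus_exclusions)
  vCyt <- unfold(imp$folds, "child_stimulus_by_cytokine",
                 config$stimulus_exclusions)
  for (nm in c("stimulus", "cytokine")) {
    v <- if (nm == "stimulus") vStim else vCyt
    pca <- runPCA(v)
    utils::write.table(
      data.frame(label = rownames(pca@scores), pca@scores[, 1:2]),
      out(paste0("pca_scores_", nm, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    artifacts <- c(artifacts, paste0("pca_scores_", nm, ".tsv"))
  }
  timings["pca"] <- tic() - t0

  # multiscale bootstrap clustering
  t0 <- tic()
  for (nm in c("stimulus", "cytokine")) {
    v <- if (nm == "stimulus") vStim else vCyt
    cs <- pvcluster(v, nBoot = config$n_boot, scales = config$scales,
                    seed = stageSeed(2L))
    exportNewick(cs, out(paste0("dendrogram_", nm, ".nwk")))
    exportSupportTable(cs, out(paste0("cluster_support_", nm, ".tsv")))
    artifacts <- c(artifacts, paste0("dendrogram_", nm, ".nwk"),
                   paste0("cluster_support_", nm, ".tsv"))
  }
  timings["cluster"] <- tic() - t0

  # cQTL scan on non-imputed folds
  scan <- NULL
  if (!is.null(geno)) {
    t0 <- tic()
    q1 <- snpQC(geno, "typed")
    q2 <- snpQC(q1$genotypes, "imputed")
    utils::write.table(rbind(q1$removed, q2$removed), out("snp_qc_removed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scan <- genomeScan(folds, q2$genotypes, config$cqtl_traits,
                       config$cqtl_threshold)
    utils::write.table(scan, out("cqtl_scan.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, "snp_qc_removed.tsv", "cqtl_scan.tsv")
    topSnp <- scan$snp[1]
    spec <- specificityProfile(topSnp, folds, q2$genotypes)
    utils::write.table(spec$summary, out("specificity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "specificity.tsv")
    if (!is.null(clinical)) {
      sig <- unique(scan$snp[scan$significant])
      if (length(sig)) {
        pa <- phenotypeAssociation(sig, q2$genotypes, clinical)
        utils::write.table(pa, out("phenotype_assoc.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        artifacts <- c(artifacts, "phenotype_assoc.tsv")
      }
    }
    timings["cqtl"] <- tic() - t0
  }

  manifest <- list(
    config_hash = configHash(config),
    seed = config$seed,
    n_children_input = nInput,
    n_children_retained = length(qrep$retained),
    exclusions = list(
      low_viability = length(qrep$excluded_low_viability),
      inadequate = length(qrep$excluded_inadequate),
      other = length(qrep$excluded_other)),
    n_significant_induction = sum(ind$significant, na.rm = TRUE),
    n_cqtl_significant = if (!is.null(scan)) sum(scan$significant) else NA,
    timings = as.list(timings),
    artifacts = lapply(artifacts, function(a)
      list(file = a, bytes = file.size(out(a)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
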