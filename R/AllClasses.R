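#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<- rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CytokineExperiment: stimulated-PBMC cytokine concentrations
#'
#' A \linkS4class{SummarizedExperiment} holding the child x cytokine x
#' stimulus concentration tensor. Each assay is one stimulus (a cytokine x
#' child matrix of concentrations in pg/mL, \code{NA} = not measured);
#' \code{colData} carries per-child \code{batch} (\code{"1"}/\code{"2"}) and
#' \code{viability} (percent); \code{rowData} carries the cytokine functional
#' group and the per-batch lower detection limits (\code{lod_batch1},
#' \code{lod_batch2}); \code{metadata(x)$stimulusPanel} is the stimulus panel
#' (name, group, culture rank, target missing rate).
#'
#' Invariants checked by the validity method: every stored concentration is
#' positive; a media assay is present; batch and viability are defined for
#' every child; assay names match the stimulus panel.
#'
#' @aliases CytokineExperiment-class
#' @exportClass CytokineExperiment
setClass("CytokineExperiment", contains = "SummarizedExperiment")

setValidity("CytokineExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("batch", "viability") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'batch' and 'viability'")
  else {
    if (anyNA(cd$batch) || !all(as.character(cd$batch) %in% c("1", "2")))
      msg <- c(msg, "batch must be '1' or '2' for every child")
    if (anyNA(cd$viability) || any(cd$viability < 0 | cd$viability > 100))
      msg <- c(msg, "viability must lie in [0, 100] for every child")
  }
  sp <- metadata(object)$stimulusPanel
  if (is.null(sp)) {
    msg <- c(msg, "metadata must contain a stimulusPanel")
  } else {
    if (!setequal(assayNames(object), sp$stimulus))
      msg <- c(msg, "assay names must match the stimulus panel")
    if (!mediaName(sp) %in% assayNames(object))
      msg <- c(msg, "media assay missing")
  }
  for (s in assayNames(object)) {
    a <- assay(object, s)
    if (any(a <= 0, na.rm = TRUE)) {
      msg <- c(msg, "all present concentrations must be > 0")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' FoldMatrix: media-normalised log2 fold inductions
#'
#' A \linkS4class{SummarizedExperiment} with one row per (cytokine, stimulus)
#' pair and one column per child. The \code{"log2fold"} assay holds
#' log2(stimulated) - log2(media) responses (\code{NA} = missing); an
#' optional \code{"imputed"} assay flags cells filled in by PPCA imputation.
#' \code{rowData} carries \code{cytokine}, \code{stimulus} and their group
#' labels. The media "stimulus" never appears as a row (it is the reference).
#'
#' @aliases FoldMatrix-class
#' @exportClass FoldMatrix
setClass("FoldMatrix", contains = "SummarizedExperiment")

setValidity("FoldMatrix", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("cytokine", "stimulus") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'cytokine' and 'stimulus'")
  if (!"log2fold" %in% assayNames(object))
    msg <- c(msg, "assay 'log2fold' required")
  sp <- metadata(object)$stimulusPanel
  if (!is.null(sp) && any(rd$stimulus == mediaName(sp)))
    msg <- c(msg, "media must not appear as a fold-induction row")
  if (length(msg)) msg else TRUE
})

#' GenotypeSet: SNP dosages with per-SNP quality metrics
#'
#' A \linkS4class{SummarizedExperiment} with one row per SNP and one column
#' per child. The \code{"dosage"} assay holds minor-allele dosages in [0, 2];
#' \code{rowData} carries \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{typed} (genotyped vs imputed), \code{call_rate}, \code{info}
#' (imputation info score), \code{maf} and \code{hwe_p}.
#'
#' @aliases GenotypeSet-class
#' @exportClass GenotypeSet
setClass("GenotypeSet", contains = "SummarizedExperiment")

setValidity("GenotypeSet", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' required")
  else {
    d <- assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  rd <- rowData(object)
  need <- c("chrom", "pos", "typed", "call_rate", "info", "maf", "hwe_p")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    if (any(rd$maf < 0 | rd$maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "MAF must lie in [0, 0.5]")
    if (any(rd$pos <= 0, na.rm = TRUE))
      msg <- c(msg, "positions must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' UnfoldedView: a 2-D unfolding of the response tensor
#'
#' Rows are composite observations (child x stimulus, child x cytokine, or
#' plain children), columns are the variables being clustered or decomposed.
#'
#' @slot values numeric matrix with dimnames.
#' @slot semantics one of \code{"child_stimulus_by_cytokine"},
#'   \code{"child_cytokine_by_stimulus"}, \code{"child_by_pair"}.
#' @slot excluded stimuli dropped from the view (e.g. polyIC).
#' @aliases UnfoldedView-class
#' @exportClass UnfoldedView
setClass("UnfoldedView", slots = c(values = "matrix", semantics = "character",
                                   excluded = "character"))

setValidity("UnfoldedView", function(object) {
  ok <- c("child_stimulus_by_cytokine", "child_cytokine_by_stimulus",
          "child_by_pair")
  msg <- character()
  if (!(length(object@semantics) == 1L && object@semantics %in% ok))
    msg <- c(msg, paste("semantics must be one of:", paste(ok, collapse = ", ")))
  dn <- dimnames(object@values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    msg <- c(msg, "values must carry row and column labels")
  else if (anyDuplicated(dn[[1]]) || anyDuplicated(dn[[2]]))
    msg <- c(msg, "row/column labels must be unique")
  if (length(msg)) msg else TRUE
})

#' PCAResult: principal component decomposition of an unfolded view
#'
#' @slot scores rows x components matrix.
#' @slot loadings columns x components orthonormal matrix.
#' @slot varianceFraction fraction of variance per component (sums to 1).
#' @slot center,scale centering/scaling record applied to columns.
#' @aliases PCAResult-class
#' @exportClass PCAResult
setClass("PCAResult", slots = c(scores = "matrix", loadings = "matrix",
                                varianceFraction = "numeric",
                                center = "numeric", scale = "numeric"))

setValidity("PCAResult", function(object) {
  vf <- object@varianceFraction
  msg <- character()
  if (any(diff(vf) > 1e-10)) msg <- c(msg, "variance fractions must be non-increasing")
  if (abs(sum(vf) - 1) > 1e-8) msg <- c(msg, "variance fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PPCAModel: probabilistic PCA fit
#'
#' Parameters of the latent Gaussian factor model
#' x = W z + mu + eps, z ~ N(0, I_k), eps ~ N(0, sigma2 I), fitted by EM on
#' the observed-data likelihood (missing entries marginalised).
#'
#' @slot W feature x k loading matrix.
#' @slot mu per-feature mean.
#' @slot sigma2 isotropic noise variance (> 0).
#' @slot k latent dimension.
#' @slot loglik observed-data log-likelihood trace over EM iterations.
#' @slot converged logical convergence flag.
#' @slot evidence approximate log model evidence per candidate k (possibly
#'   empty; filled by \code{\link{selectDimensionality}}).
#' @aliases PPCAModel-class
#' @exportClass PPCAModel
setClass("PPCAModel", slots = c(W = "matrix", mu = "numeric",
                                sigma2 = "numeric", k = "integer",
                                loglik = "numeric", converged = "logical",
                                evidence = "numeric"))

setValidity("PPCAModel", function(object) {
  msg <- character()
  if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be > 0")
  if (object@k < 1L || object@k != ncol(object@W))
    msg <- c(msg, "k must equal ncol(W) and be >= 1")
  if (length(object@loglik) > 1 && any(diff(object@loglik) < -1e-8))
    msg <- c(msg, "log-likelihood must be non-decreasing over EM iterations")
  if (length(msg)) msg else TRUE
})

#' ClusterSupport: dendrogram with multiscale bootstrap node support
#'
#' @slot hclust the observed \code{\link[stats]{hclust}} tree.
#' @slot table per-internal-node data.frame: node id, leaf set, height,
#'   \code{au}, \code{bp} (scale-1 frequency), fitted \code{v}, \code{c},
#'   weighted \code{fit_rss}, degeneracy flag, highly-supported flag.
#' @slot bpByScale node x scale matrix of bootstrap frequencies.
#' @slot scales row-resampling fractions r (tau = sqrt(n/ceil(r n))).
#' @slot nBoot replicates per scale.
#' @slot seed RNG seed used for the replicate stream.
#' @aliases ClusterSupport-class
#' @exportClass ClusterSupport
setClass("ClusterSupport", slots = c(hclust = "ANY", table = "data.frame",
                                     bpByScale = "matrix", scales = "numeric",
                                     nBoot = "integer", seed = "integer"))

setValidity("ClusterSupport", function(object) {
  msg <- character()
  pr <- c(object@bpByScale, object@table$au, object@table$bp)
  if (any(pr < -1e-12 | pr > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CytokineExperiment", function(object) {
  cat("CytokineExperiment:", nrow(object), "cytokines x", ncol(object),
      "children x", length(assayNames(object)), "stimuli\n")
  cat("  batches:", paste(names(table(colData(object)$batch)),
                          table(colData(object)$batch), sep = ":", collapse = " "), "\n")
  nm <- vapply(assays(object), function(a) mean(is.na(a)), numeric(1))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(nm)))
})

setMethod("show", "FoldMatrix", function(object) {
  cat("FoldMatrix:", nrow(object), "cytokine-stimulus pairs x", ncol(object),
      "children\n")
  cat(sprintf("  missing: %.1f%%", 100 * mean(is.na(assay(object, "log2fold")))))
  if ("imputed" %in% assayNames(object))
    cat(sprintf("  (%.1f%% imputed)", 100 * mean(assay(object, "imputed"))))
  cat("\n")
})

setMethod("show", "GenotypeSet", function(object) {
  cat("GenotypeSet:", nrow(object), "SNPs x", ncol(object), "children;",
      sum(rowData(object)$typed), "genotyped,", sum(!rowData(object)$typed),
      "imputed\n")
})

setMethod("show", "UnfoldedView", function(object) {
  cat("UnfoldedView [", object@semantics, "]: ", nrow(object@values), " x ",
      ncol(object@values), "\n", sep = "")
  if (length(object@excluded))
    cat("  excluded stimuli:", paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "PPCAModel", function(object) {
  cat("PPCAModel: k =", object@k, " sigma2 =", signif(object@sigma2, 4),
      " logLik =", signif(utils::tail(object@loglik, 1), 8),
      if (object@converged) "(converged)\n" else "(max iterations)\n")
})

setMethod("show", "ClusterSupport", function(object) {
  cat("ClusterSupport:", nrow(object@table), "internal nodes;",
      sum(object@table$highly_supported), "with AU > 0.95;",
      length(object@scales), "scales x", object@nBoot, "replicates\n")
})
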