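#' Unfold the child x cytokine x stimulus fold tensor into a matrix view
#'
#' Three unfoldings are supported: \code{child_stimulus_by_cytokine} (one
#' row per child-stimulus combination, columns = cytokines; used to cluster
#' cytokines), \code{child_cytokine_by_stimulus} (one row per
#' child-cytokine combination, columns = stimuli; used to cluster stimuli)
#' and \code{child_by_pair} (one row per child, columns = cytokine-stimulus
#' pairs; used for child-level substructure). Excluded stimuli (by default
#' polyIC, following its contamination history) are absent everywhere.
#'
#' @param folds a \linkS4class{FoldMatrix}.
#' @param semantics one of the three axis layouts above.
#' @param stimulusExclusions stimuli to drop (default \code{"polyIC"}).
#' @param cytokineSubset,stimulusSubset optional restrictions (e.g. a
#'   functional subgroup) applied before unfolding.
#' @return an \linkS4class{UnfoldedView}.
#' @examples
#' \dontrun{
#' v <- unfold(folds, "child_cytokine_by_stimulus")
#' ncol(v@values)  # 14 stimuli under default panels with polyIC excluded
#' }
#' @export
unfold <- function(folds, semantics = c("child_stimulus_by_cytokine",
                                        "child_cytokine_by_stimulus",
                                        "child_by_pair"),
                   stimulusExclusions = "polyIC",
                   cytokineSubset = NULL, stimulusSubset = NULL) {
  semantics <- match.arg(semantics)
  sp <- stimulusPanel(folds)
  unknown <- setdiff(stimulusExclusions, sp$stimulus)
  if (length(unknown))
    stop("unknown exclusion name: ", paste(unknown, collapse = ", "))
  rd <- rowData(folds)
  keep <- !(rd$stimulus %in% stimulusExclusions)
  if (!is.null(cytokineSubset)) keep <- keep & rd$cytokine %in% cytokineSubset
  if (!is.null(stimulusSubset)) keep <- keep & rd$stimulus %in% stimulusSubset
  m <- assay(folds, "log2fold")[keep, , drop = FALSE]
  rd <- rd[keep, , drop = FALSE]
  kids <- colnames(m)
  cyt <- unique(rd$cytokine)
  stim <- unique(rd$stimulus)

  vals <- switch(semantics,
    child_by_pair = {
      v <- t(m)
      v
    },
    child_stimulus_by_cytokine = {
      v <- matrix(NA_real_, length(kids) * length(stim), length(cyt),
                  dimnames = list(paste(rep(kids, each = length(stim)),
                                        rep(stim, length(kids)), sep = ":"),
                                  cyt))
      for (i in seq_len(nrow(m)))
        v[paste(kids, rd$stimulus[i], sep = ":"), rd$cytokine[i]] <- m[i, ]
      v
    },
    child_cytokine_by_stimulus = {
      v <- matrix(NA_real_, length(kids) * length(cyt), length(stim),
                  dimnames = list(paste(rep(kids, each = length(cyt)),
                                        rep(cyt, length(kids)), sep = ":"),
                                  stim))
      for (i in seq_len(nrow(m)))
        v[paste(kids, rd$cytokine[i], sep = ":"), rd$stimulus[i]] <- m[i, ]
      v
    })
  new("UnfoldedView", values = vals, semantics = semantics,
      excluded = as.character(stimulusExclusions))
}

#' Refold a view back into the pair x child layout
#'
#' Inverse of \code{\link{unfold}} over the pairs the view retained; used to
#' verify that unfolding neither duplicates nor loses values.
#'
#' @param view an \linkS4class{UnfoldedView}.
#' @return a pair x child matrix with rows named "cytokine.stimulus".
#' @export
refold <- function(view) {
  v <- view@values
  if (view@semantics == "child_by_pair") return(t(v))
  parts <- do.call(rbind, strsplit(rownames(v), ":", fixed = TRUE))
  kids <- unique(parts[, 1])
  other <- unique(parts[, 2])
  pairs <- if (view@semantics == "child_stimulus_by_cytokine")
    expand.grid(cytokine = colnames(v), stimulus = other,
                stringsAsFactors = FALSE)
  else
    expand.grid(cytokine = other, stimulus = colnames(v),
                stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nrow(pairs), length(kids),
                dimnames = list(paste(pairs$cytokine, pairs$stimulus,
                                      sep = "."), kids))
  for (i in seq_len(nrow(v))) {
    child <- parts[i, 1]
    if (view@semantics == "child_stimulus_by_cytokine")
      out[paste(colnames(v), parts[i, 2], sep = "."), child] <- v[i, ]
    else
      out[paste(parts[i, 2], colnames(v), sep = "."), child] <- v[i, ]
  }
  out
}

#' Principal component analysis of an unfolded view
#'
#' Column-centred (optionally unit-variance scaled) singular value
#' decomposition. Variance fractions are the normalised squared singular
#' values. Values must be complete (impute first).
#'
#' @param view an \linkS4class{UnfoldedView} or plain matrix.
#' @param scaleColumns standardise columns to unit variance (default FALSE:
#'   the values already share the log2 fold scale).
#' @return a \linkS4class{PCAResult}.
#' @export
runPCA <- function(view, scaleColumns = FALSE) {
  m <- if (is(view, "UnfoldedView")) view@values else as.matrix(view)
  if (anyNA(m)) stop("missing values present; impute before PCA")
  if (nrow(m) < 2) stop("need at least 2 rows")
  pr <- stats::prcomp(m, center = TRUE, scale. = scaleColumns)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  new("PCAResult", scores = pr$x, loadings = pr$rotation,
      varianceFraction = vf, center = pr$center,
      scale = if (isFALSE(pr$scale)) rep(1, ncol(m)) else pr$scale)
}

#' Pairwise Pearson correlations with p-values
#'
#' Pairwise-complete Pearson correlation between the columns of a view,
#' with p-values from the t transform t = r sqrt(n-2) / sqrt(1-r^2)
#' (two-sided). Columns with zero variance yield NA entries.
#'
#' @param view an \linkS4class{UnfoldedView} or matrix.
#' @param minPairs minimum complete pairs per cell (default 3; fewer yields
#'   NA).
#' @return list with symmetric matrices \code{r}, \code{p} and \code{n}.
#' @export
pairwisePearson <- function(view, minPairs = 3L) {
  m <- if (is(view, "UnfoldedView")) view@values else as.matrix(view)
  d <- ncol(m)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  nm <- crossprod(!is.na(m))
  r[nm < minPairs] <- NA
  tstat <- r * sqrt(pmax(nm - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = pmax(nm - 2, 1), lower.tail = FALSE)
  p[!is.finite(p)] <- ifelse(abs(r[!is.finite(p)]) >= 1, 0, NA)
  diag(r) <- 1
  diag(p) <- NA
  list(r = r, p = p, n = nm)
}
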