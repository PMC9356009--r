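#' Correlation distance between the columns of a view
#'
#' d(i, j) = 1 - Pearson(column i, column j); symmetric, zero diagonal,
#' range [0, 2]. The matrix must be complete (clustering runs on imputed
#' data) and every column must have nonzero variance.
#'
#' @param view an \linkS4class{UnfoldedView} or matrix (rows = observations,
#'   columns = items to cluster).
#' @return a symmetric distance matrix.
#' @export
correlationDistance <- function(view) {
  m <- if (is(view, "UnfoldedView")) view@values else as.matrix(view)
  if (anyNA(m)) stop("missing values present; impute before clustering")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin wrapper over \code{\link[stats]{hclust}} with
#' \code{method = "average"} on a symmetric distance matrix. The merge
#' sequence is deterministic for a given distance matrix.
#'
#' @param d symmetric distance matrix (or \code{dist}).
#' @return an \code{hclust} object.
#' @export
averageLinkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Leaf sets beneath every internal node of an hclust tree
#'
#' @param hc an \code{hclust} object.
#' @return list of integer vectors (sorted leaf indices), one per internal
#'   node in merge order.
#' @export
nodeLeafSets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    sets[[i]] <- sort(c(if (l < 0) -l else sets[[l]],
                        if (r < 0) -r else sets[[r]]))
  }
  sets
}

leafSetKeys <- function(sets) {
  vapply(sets, paste, character(1), collapse = ",")
}

#' Multiscale bootstrap frequencies for the observed dendrogram
#'
#' Clusters the columns of \code{view} (correlation distance, average
#' linkage), then for each scale r resamples ceiling(r * n) of the n rows
#' with replacement \code{nBoot} times, reclusters, and records for each
#' observed internal node the fraction of replicates whose tree contains
#' the identical leaf set (the per-scale bootstrap probability, BP). The
#' scale parameter entering the AU fit is tau = sqrt(n / n'), where n' is
#' the resampled row count.
#'
#' The replicate stream is a single seeded RNG sequence: scales in the given
#' order, \code{nBoot} draws of \code{sample.int(n, n', replace = TRUE)}
#' each, so any replicate set can be reproduced independently.
#'
#' @param view an \linkS4class{UnfoldedView} or matrix.
#' @param nBoot bootstrap replicates per scale (>= 100).
#' @param scales row-resampling fractions r (each r * n must be >= 3).
#' @param seed integer RNG seed.
#' @return list with \code{hclust}, \code{leafSets}, \code{bpByScale}
#'   (node x scale), \code{tau}, \code{scales}, \code{nBoot}, \code{seed}.
#' @export
bootstrapSupport <- function(view, nBoot = 1000L,
                             scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  m <- if (is(view, "UnfoldedView")) view@values else as.matrix(view)
  n <- nrow(m)
  if (nBoot < 100L) stop("nBoot must be >= 100")
  if (any(ceiling(scales * n) < 3)) stop("too few rows at the smallest scale")
  hc <- averageLinkage(correlationDistance(m))
  sets <- nodeLeafSets(hc)
  keys <- leafSetKeys(sets)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(keys, paste0("r", scales)))
  set.seed(as.integer(seed))
  for (si in seq_along(scales)) {
    np <- as.integer(ceiling(scales[si] * n))
    hits <- numeric(length(keys))
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, np, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      db <- 1 - suppressWarnings(stats::cor(mb))
      db[!is.finite(db)] <- 1  # constant column in a replicate: treat as uncorrelated
      diag(db) <- 0
      hcb <- stats::hclust(stats::as.dist(db), method = "average")
      kb <- leafSetKeys(nodeLeafSets(hcb))
      hits <- hits + (keys %in% kb)
    }
    bp[, si] <- hits / nBoot
  }
  list(hclust = hc, leafSets = sets, bpByScale = bp,
       tau = sqrt(n / ceiling(scales * n)), scales = scales,
       nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Approximately-unbiased probability from a multiscale BP curve
#'
#' Transforms each per-scale bootstrap probability to
#' z(tau) = qnorm(1 - BP) and fits the signed-distance/curvature model
#' z = v * tau + c / tau by weighted least squares with binomial weights
#' nBoot * dnorm(z)^2 / (BP (1 - BP)). The approximately-unbiased
#' probability is AU = 1 - pnorm(v - c); the fitted ordinary BP at tau = 1
#' is 1 - pnorm(v + c), so a zero-curvature fit collapses AU onto BP.
#' Curves that are all 0 or all 1 across scales are degenerate: AU is 0 or
#' 1 with a flag and no fit.
#'
#' @param bp per-scale bootstrap frequencies.
#' @param tau per-scale tau = sqrt(n / n').
#' @param nBoot replicates per scale (for clipping and weights).
#' @return list: au, bp_fitted (at tau = 1), v, c, fit_rss (weighted),
#'   degenerate, n_scales_used.
#' @export
auProbability <- function(bp, tau, nBoot) {
  if (all(bp <= 0)) return(list(au = 0, bp_fitted = 0, v = NA_real_,
                                c = NA_real_, fit_rss = NA_real_,
                                degenerate = TRUE, n_scales_used = 0L))
  if (all(bp >= 1)) return(list(au = 1, bp_fitted = 1, v = NA_real_,
                                c = NA_real_, fit_rss = NA_real_,
                                degenerate = TRUE, n_scales_used = 0L))
  eps <- 1 / (nBoot + 1)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  use <- which(bpc > 0 & bpc < 1)
  if (length(use) < 3)
    return(list(au = NA_real_, bp_fitted = NA_real_, v = NA_real_,
                c = NA_real_, fit_rss = NA_real_, degenerate = TRUE,
                n_scales_used = length(use)))
  z <- stats::qnorm(1 - bpc[use])
  X <- cbind(v = tau[use], c = 1 / tau[use])
  w <- nBoot * stats::dnorm(z)^2 / (bpc[use] * (1 - bpc[use]))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients["v"]); cc <- unname(fit$coefficients["c"])
  list(au = 1 - stats::pnorm(v - cc),
       bp_fitted = 1 - stats::pnorm(v + cc),
       v = v, c = cc,
       fit_rss = sum(w * fit$residuals^2),
       degenerate = FALSE, n_scales_used = length(use))
}

#' Hierarchical clustering with AU/BP cluster support
#'
#' Composition of \code{\link{correlationDistance}},
#' \code{\link{averageLinkage}}, \code{\link{bootstrapSupport}} and
#' \code{\link{auProbability}}: clusters the columns of a view and attaches,
#' to every internal dendrogram node, the ordinary bootstrap probability at
#' scale 1 (BP) and the multiscale approximately-unbiased probability (AU).
#' Nodes with AU > 0.95 are marked highly supported.
#'
#' @inheritParams bootstrapSupport
#' @return a \linkS4class{ClusterSupport}.
#' @export
pvcluster <- function(view, nBoot = 1000L,
                      scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  bs <- bootstrapSupport(view, nBoot = nBoot, scales = scales, seed = seed)
  labels <- bs$hclust$labels
  scale1 <- which.min(abs(bs$scales - 1))
  rows <- lapply(seq_along(bs$leafSets), function(i) {
    fit <- auProbability(bs$bpByScale[i, ], bs$tau, bs$nBoot)
    data.frame(node = i,
               leaves = paste(labels[bs$leafSets[[i]]], collapse = ","),
               n_leaves = length(bs$leafSets[[i]]),
               height = bs$hclust$height[i],
               au = fit$au, bp = bs$bpByScale[i, scale1],
               v = fit$v, c = fit$c, fit_rss = fit$fit_rss,
               degenerate = fit$degenerate,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$highly_supported <- !is.na(tab$au) & tab$au > 0.95
  new("ClusterSupport", hclust = bs$hclust, table = tab,
      bpByScale = bs$bpByScale, scales = bs$scales, nBoot = bs$nBoot,
      seed = bs$seed)
}

#' Support value for the node matching a given leaf set
#'
#' @param support a \linkS4class{ClusterSupport}.
#' @param leaves character vector of leaf labels.
#' @return one row of the support table, or NULL when no node carries
#'   exactly this leaf set.
#' @export
nodeSupport <- function(support, leaves) {
  key <- paste(sort(leaves), collapse = ",")
  tab <- support@table
  keys <- vapply(strsplit(tab$leaves, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  hit <- which(keys == key)
  if (!length(hit)) return(NULL)
  tab[hit, , drop = FALSE]
}

#' Export a supported dendrogram as Newick with AU|BP node labels
#'
#' Internal nodes are labelled "AU|BP" as percentages (one decimal); branch
#' lengths are height differences, so the tree is ultrametric.
#'
#' @param support a \linkS4class{ClusterSupport}.
#' @param path output file (NULL returns the string).
#' @return the Newick string, invisibly when written to a file.
#' @export
exportNewick <- function(support, path = NULL) {
  hc <- support@hclust
  tab <- support@table
  lab <- function(i) sprintf("%.1f|%.1f", 100 * tab$au[i], 100 * tab$bp[i])
  build <- function(node, parentH) {
    if (node < 0) {
      sprintf("%s:%.10g", hc$labels[-node], parentH)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s)%s:%.10g", build(hc$merge[node, 1], h),
              build(hc$merge[node, 2], h), lab(node), parentH - h)
    }
  }
  n <- length(hc$order)
  root <- n - 1L
  h <- hc$height[root]
  s <- sprintf("(%s,%s)%s;", build(hc$merge[root, 1], h),
               build(hc$merge[root, 2], h), lab(root))
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Flat TSV export of a support table
#' @param support a \linkS4class{ClusterSupport}.
#' @param path output TSV file.
#' @export
exportSupportTable <- function(support, path) {
  utils::write.table(support@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
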