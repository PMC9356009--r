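#' @useDynLib cytoResponse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fit probabilistic PCA by EM with missing data
#'
#' Fits the latent Gaussian factor model x = W z + mu + eps
#' (z ~ N(0, I_k), eps ~ N(0, sigma2 I)) by expectation-maximisation on the
#' observed-data likelihood: missing entries are marginalised, so each row
#' contributes a Gaussian over its observed coordinates only. The EM is
#' initialised from the observed column means and the SVD of the mean-filled
#' matrix; additional restarts perturb that start, and the fit with the best
#' final likelihood is kept. The log-likelihood is guaranteed non-decreasing
#' across iterations.
#'
#' @param x numeric matrix (rows = samples, columns = features); \code{NA} =
#'   missing. Every row and column must have at least one observed value.
#' @param k latent dimension, 1 <= k < min(nrow, ncol).
#' @param seed integer seed for the restart perturbations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param nRestarts number of initialisations (first is deterministic).
#' @return a \linkS4class{PPCAModel}.
#' @export
fitPPCA <- function(x, k, seed = 1L, tol = 1e-6, maxIter = 1000L,
                    nRestarts = 3L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (k < 1 || k >= min(n, d)) stop("k out of range: need 1 <= k < min(n, d)")
  if (any(rowSums(!is.na(x)) == 0)) stop("row with no observed value")
  if (any(colSums(!is.na(x)) == 0)) stop("column with no observed value")

  mu0 <- colMeans(x, na.rm = TRUE)
  xf <- x
  for (j in seq_len(d)) xf[is.na(xf[, j]), j] <- mu0[j]
  xc <- sweep(xf, 2, mu0)
  sv <- svd(xc, nu = 0, nv = k)
  lambda <- (svd(xc, nu = 0, nv = 0)$d^2) / n
  s20 <- max(mean(lambda[(k + 1):length(lambda)]), 1e-6)
  W0 <- sv$v %*% diag(sqrt(pmax(lambda[seq_len(k)] - s20, 1e-3)), k, k)

  best <- NULL
  for (r in seq_len(nRestarts)) {
    if (r == 1L) {
      Wr <- W0
    } else {
      set.seed(seed + r)
      Wr <- W0 + matrix(stats::rnorm(d * k, sd = 0.1 * stats::sd(W0)), d, k)
    }
    fit <- ppca_em_cpp(x, Wr, mu0, s20, as.integer(maxIter), tol)
    if (is.null(best) || utils::tail(fit$loglik, 1) > utils::tail(best$loglik, 1))
      best <- fit
  }
  W <- best$W
  dimnames(W) <- list(colnames(x), paste0("LV", seq_len(k)))
  new("PPCAModel", W = W, mu = stats::setNames(drop(best$mu), colnames(x)),
      sigma2 = best$sigma2, k = as.integer(k),
      loglik = as.numeric(best$loglik), converged = best$converged,
      evidence = numeric())
}

#' Laplace-approximation log evidence for the PPCA dimension
#'
#' Minka's automatic dimensionality criterion: an approximate log marginal
#' likelihood of the k-dimensional PPCA model computed from the eigenvalues
#' of the sample covariance.
#'
#' @param lambda eigenvalues of the sample covariance, decreasing.
#' @param n number of samples.
#' @param k candidate dimension, 1 <= k < length(lambda).
#' @return approximate log evidence (additive constants shared across k).
#' @export
minkaEvidence <- function(lambda, n, k) {
  d <- length(lambda)
  stopifnot(k >= 1, k < d)
  lambda <- pmax(lambda, 1e-12)
  i <- seq_len(k)
  pu <- -k * log(2) + sum(lgamma((d - i + 1) / 2) -
                            ((d - i + 1) / 2) * log(pi))
  pl <- -n / 2 * sum(log(lambda[i]))
  v <- mean(lambda[(k + 1):d])
  pv <- -n * (d - k) / 2 * log(v)
  m <- d * k - k * (k + 1) / 2
  pp <- (m + k) / 2 * log(2 * pi)
  lt <- lambda
  lt[(k + 1):d] <- v
  pa <- 0
  for (ii in i) {
    jj <- (ii + 1):d
    pa <- pa + sum(log(pmax(lambda[ii] - lambda[jj], 1e-12)) +
                     log(pmax(1 / lt[jj] - 1 / lt[ii], 1e-12)) + log(n))
  }
  pu + pl + pv + pp - pa / 2 - k / 2 * log(n)
}

#' Select the PPCA latent dimension by Bayesian model selection
#'
#' Evaluates the Laplace-approximation log evidence
#' (\code{\link{minkaEvidence}}) over candidate dimensions on the sample
#' covariance of the (mean-filled, if incomplete) matrix and returns the
#' maximiser together with the full evidence curve for audit.
#'
#' @param x numeric matrix, \code{NA} allowed.
#' @param kCandidates candidate dimensions (default 1 .. min(n, d) - 1,
#'   capped at 15).
#' @return list with \code{k} (the selected dimension) and \code{evidence}
#'   (named numeric over candidates).
#' @export
selectDimensionality <- function(x, kCandidates = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (is.null(kCandidates))
    kCandidates <- seq_len(min(min(n, d) - 1L, 15L))
  if (!length(kCandidates) || any(kCandidates < 1 | kCandidates >= min(n, d)))
    stop("no valid candidate dimension")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(d)) x[is.na(x[, j]), j] <- mu[j]
  xc <- sweep(x, 2, mu)
  lambda <- svd(xc, nu = 0, nv = 0)$d^2 / n
  if (length(lambda) < d) lambda <- c(lambda, rep(0, d - length(lambda)))
  ev <- vapply(kCandidates, function(k) minkaEvidence(lambda, n, k),
               numeric(1))
  names(ev) <- kCandidates
  list(k = kCandidates[which.max(ev)], evidence = ev)
}

#' Impute missing cells by their conditional expectation under a PPCA model
#'
#' For each row, the latent score is inferred from the observed coordinates
#' (posterior mean), and each missing coordinate is replaced by
#' mu + W z. Observed cells are untouched; a fully-missing row is imputed
#' to mu (no evidence).
#'
#' @param x matrix the model was fitted on (same feature set).
#' @param model a \linkS4class{PPCAModel}.
#' @return the completed matrix.
#' @export
imputePPCA <- function(x, model) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model@W))
    stop("feature mismatch between matrix and model")
  W <- model@W; mu <- model@mu; s2 <- model@sigma2
  k <- model@k
  out <- x
  for (i in which(rowSums(is.na(x)) > 0)) {
    o <- which(!is.na(x[i, ]))
    m <- which(is.na(x[i, ]))
    if (length(o)) {
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(s2, k)
      z <- solve(M, crossprod(Wo, x[i, o] - mu[o]))
      out[i, m] <- mu[m] + W[m, , drop = FALSE] %*% z
    } else {
      out[i, m] <- mu[m]
    }
  }
  out
}

#' Validate PPCA imputation against per-feature mean imputation
#'
#' Simulated-missingness comparison: per replicate, a fresh random subset of
#' the observed cells is masked at the study's missing rate, both methods
#' impute the masked matrix, and the root-mean-square error is computed on
#' the masked cells only (the same cells for both methods).
#'
#' @param x numeric matrix (log2 fold scale), \code{NA} allowed.
#' @param missingRate fraction of observed cells to mask, in (0, 1).
#' @param nReplicates number of replicates.
#' @param seed RNG seed.
#' @param kCandidates candidates for per-replicate dimension selection
#'   (default 1..8).
#' @param nRestarts EM restarts per fit (1 keeps the validation fast; the
#'   deterministic SVD start is already good).
#' @return data.frame with columns replicate, method (ppca/mean), rmse, plus
#'   attributes \code{missing_rate} and \code{seed}.
#' @export
validateImputation <- function(x, missingRate, nReplicates = 100L, seed = 1L,
                               kCandidates = 1:8, nRestarts = 1L) {
  if (missingRate <= 0 || missingRate >= 1)
    stop("missingRate must lie in (0, 1)")
  x <- as.matrix(x)
  obsCells <- which(!is.na(x))
  nMask <- max(1L, round(missingRate * length(obsCells)))
  set.seed(seed)
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    repeat {
      mask <- sample(obsCells, nMask)
      xm <- x
      xm[mask] <- NA
      if (all(rowSums(!is.na(xm)) > 0) && all(colSums(!is.na(xm)) > 0))
        break
    }
    kc <- kCandidates[kCandidates < min(dim(xm))]
    k <- selectDimensionality(xm, kc)$k
    fit <- fitPPCA(xm, k, seed = seed + r, nRestarts = nRestarts)
    imp <- imputePPCA(xm, fit)
    rmsePPCA <- sqrt(mean((imp[mask] - x[mask])^2))
    mu <- colMeans(xm, na.rm = TRUE)
    impMean <- xm
    for (j in seq_len(ncol(xm))) impMean[is.na(xm[, j]), j] <- mu[j]
    rmseMean <- sqrt(mean((impMean[mask] - x[mask])^2))
    out[[r]] <- data.frame(replicate = r, method = c("ppca", "mean"),
                           rmse = c(rmsePPCA, rmseMean))
  }
  res <- do.call(rbind, out)
  attr(res, "missing_rate") <- missingRate
  attr(res, "seed") <- seed
  res
}

#' Impute a FoldMatrix by PPCA on the child x pair unfolding
#'
#' Selects the latent dimension by Bayesian model selection, fits PPCA by
#' EM, and fills missing log2 fold inductions with their conditional
#' expectations. The result carries an \code{"imputed"} indicator assay.
#'
#' @param folds a \linkS4class{FoldMatrix}.
#' @param kCandidates candidate latent dimensions (default 1..10).
#' @param seed RNG seed for EM restarts.
#' @param ... passed to \code{\link{fitPPCA}}.
#' @return list with \code{folds} (completed \linkS4class{FoldMatrix}) and
#'   \code{model} (the fitted \linkS4class{PPCAModel} with its evidence
#'   curve).
#' @export
imputeFolds <- function(folds, kCandidates = 1:10, seed = 1L, ...) {
  m <- foldValues(folds)  # child x pair
  hasData <- rowSums(!is.na(m)) > 0
  mFit <- m[hasData, , drop = FALSE]  # children with no pair at all carry
                                      # no evidence; they are imputed to mu
  kc <- kCandidates[kCandidates < min(dim(mFit))]
  sel <- selectDimensionality(mFit, kc)
  fit <- fitPPCA(mFit, sel$k, seed = seed, ...)
  fit@evidence <- sel$evidence
  comp <- imputePPCA(m, fit)
  imputedFlag <- t(is.na(m))
  out <- FoldMatrix(t(comp),
                    data.frame(cytokine = rowData(folds)$cytokine,
                               stimulus = rowData(folds)$stimulus),
                    stimulusPanel(folds), cytokinePanel(folds),
                    imputed = imputedFlag)
  list(folds = out, model = fit)
}
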