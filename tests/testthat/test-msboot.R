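test_that("correlation distance matches the Pearson formula", {
  set.seed(1)
  m <- cbind(a = rnorm(4), b = rnorm(4))
  m <- cbind(m, c = m[, "a"], d = -m[, "a"])
  rownames(m) <- paste0("r", 1:4)
  d <- correlationDistance(m)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 2)
  expect_equal(unname(diag(d)), rep(0, 4))
  # direct formula oracle on a toy 4-row pair
  x <- m[, "a"]; y <- m[, "b"]
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(d["a", "b"], 1 - rHand, tolerance = 1e-12)
  m2 <- cbind(m, e = rep(1, 4))
  expect_error(correlationDistance(m2), "zero-variance")
  expect_error(correlationDistance(cbind(m[, 1], c(NA, 1, 2, 3))), "missing")
})

test_that("average linkage follows the 3-point UPGMA recurrence", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- averageLinkage(d)
  # merge (A,B) at height 1, then C joins at mean(d(A,C), d(B,C)) = 4
  expect_equal(hc$height, c(1, 4))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
  sets <- nodeLeafSets(hc)
  expect_equal(length(sets), 2)
  expect_equal(sort(hc$labels[sets[[1]]]), c("A", "B"))
  # all-equal distances: a chain with equal heights
  dEq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dEq) <- 0
  hcEq <- averageLinkage(dEq)
  expect_equal(unname(hcEq$height), rep(1, 3))
  # n leaves -> n - 1 merges
  set.seed(2)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("r", 1:10),
                                                paste0("c", 1:6)))
  expect_equal(nrow(averageLinkage(correlationDistance(m))$merge), 5)
  expect_error(averageLinkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dendrogram is invariant to row order of the input", {
  set.seed(3)
  m <- twoBlockMatrix(60, 10, 0.8)
  hc1 <- averageLinkage(correlationDistance(m))
  hc2 <- averageLinkage(correlationDistance(m[sample(nrow(m)), ]))
  expect_identical(hc1$merge, hc2$merge)
  expect_equal(hc1$height, hc2$height)
})

test_that("bootstrap frequencies reflect planted column structure", {
  set.seed(4)
  m <- twoBlockMatrix(100, 12, 0.9)
  bs <- bootstrapSupport(m, nBoot = 200, scales = c(0.6, 1, 1.4), seed = 9)
  key1 <- paste(1:6, collapse = ",")
  key2 <- paste(7:12, collapse = ",")
  expect_true(all(bs$bpByScale[key1, ] > 0.95))
  expect_true(all(bs$bpByScale[key2, ] > 0.95))
  # i.i.d. noise: internal nodes are unstable
  set.seed(5)
  mN <- matrix(rnorm(100 * 10), 100, 10,
               dimnames = list(paste0("r", 1:100), paste0("c", 1:10)))
  bsN <- bootstrapSupport(mN, nBoot = 200, scales = 1, seed = 9)
  inner <- bsN$bpByScale[-nrow(bsN$bpByScale), 1]  # root always present
  expect_gt(mean(inner < 0.5), 0.6)
  # duplicated columns pair with certainty at scale 1
  mD <- cbind(mN[, 1:3], mN[, 1:3] + 1e-9)
  colnames(mD) <- c("a", "b", "c", "a2", "b2", "c2")
  bsD <- bootstrapSupport(mD, nBoot = 150, scales = 1, seed = 2)
  for (pair in list(c(1L, 4L), c(2L, 5L), c(3L, 6L))) {
    key <- paste(pair, collapse = ",")
    if (key %in% rownames(bsD$bpByScale))
      expect_equal(unname(bsD$bpByScale[key, 1]), 1)
  }
  expect_error(bootstrapSupport(m, nBoot = 50), "nBoot")
  expect_error(bootstrapSupport(m[1:4, ], nBoot = 100, scales = 0.5),
               "too few rows")
})

test_that("BP at scale 1 equals an independently coded bootstrap loop", {
  set.seed(6)
  m <- twoBlockMatrix(50, 8, 0.7)
  nb <- 150L
  bs <- bootstrapSupport(m, nBoot = nb, scales = 1, seed = 42)
  # independent loop: same seed stream, own clustering + leaf-set code
  leafSetsOf <- function(hc) {
    n <- length(hc$order)
    out <- vector("list", n - 1)
    for (i in seq_len(n - 1)) {
      kids <- lapply(hc$merge[i, ], function(j)
        if (j < 0) -j else out[[j]])
      out[[i]] <- sort(unlist(kids))
    }
    vapply(out, paste, character(1), collapse = ",")
  }
  obsKeys <- leafSetsOf(stats::hclust(stats::as.dist(1 - stats::cor(m)),
                                      method = "average"))
  counts <- setNames(numeric(length(obsKeys)), obsKeys)
  set.seed(42L)
  for (b in seq_len(nb)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    db <- 1 - stats::cor(m[idx, ])
    db[!is.finite(db)] <- 1
    diag(db) <- 0
    kb <- leafSetsOf(stats::hclust(stats::as.dist(db), method = "average"))
    counts <- counts + (obsKeys %in% kb)
  }
  expect_identical(unname(bs$bpByScale[, 1]), unname(counts / nb))
})

test_that("AU fit collapses to BP at zero curvature and recovers planted (v, c)", {
  tau <- 1 / sqrt(seq(0.5, 1.4, by = 0.1))
  # a curve generated with zero curvature: the fit returns c = 0 and the
  # model collapses, AU = fitted BP at tau = 1
  v0 <- -0.8416
  fit0 <- auProbability(1 - pnorm(v0 * tau), tau, 1000)
  expect_lt(abs(fit0$c), 1e-6)
  expect_equal(fit0$v, v0, tolerance = 1e-4)
  expect_equal(fit0$au, fit0$bp_fitted, tolerance = 1e-6)
  expect_equal(fit0$au, 1 - pnorm(v0), tolerance = 1e-4)
  # planted signed distance / curvature with binomial noise
  set.seed(7)
  v <- -1.0; cc <- 0.3; nb <- 10000
  bpTrue <- 1 - pnorm(v * tau + cc / tau)
  bpObs <- rbinom(length(tau), nb, bpTrue) / nb
  fit <- auProbability(bpObs, tau, nb)
  expect_lt(abs(fit$v - v), 0.05)
  expect_lt(abs(fit$c - cc), 0.05)
  expect_lt(abs(fit$au - (1 - pnorm(v - cc))), 0.01)
  # degenerate curves
  d1 <- auProbability(rep(1, 10), tau, 1000)
  expect_equal(d1$au, 1)
  expect_true(d1$degenerate)
  d0 <- auProbability(rep(0, 10), tau, 1000)
  expect_equal(d0$au, 0)
  expect_true(d0$degenerate)
  few <- auProbability(c(0.4, 0.6), tau[1:2], 1000)
  expect_true(is.na(few$au))
  expect_true(few$degenerate)
})

test_that("pvcluster composes the pieces deterministically and flags AU > 0.95", {
  set.seed(8)
  m <- twoBlockMatrix(80, 10, 0.9)
  cs1 <- pvcluster(m, nBoot = 150, seed = 3)
  cs2 <- pvcluster(m, nBoot = 150, seed = 4)
  # observed tree identical across bootstrap seeds
  expect_identical(cs1@hclust$merge, cs2@hclust$merge)
  b1 <- nodeSupport(cs1, paste0("v", sprintf("%02d", 1:5)))
  expect_true(!is.null(b1) && b1$au > 0.95 && b1$highly_supported)
  # AU-BP consistency for well-fit nodes: fitted BP at tau = 1 within
  # 3 binomial SEs of the observed scale-1 frequency
  tab <- cs1@table
  ok <- !tab$degenerate & !is.na(tab$au)
  bpFit <- 1 - pnorm(tab$v[ok] + tab$c[ok])
  se <- sqrt(pmax(tab$bp[ok] * (1 - tab$bp[ok]), 1e-4) / cs1@nBoot)
  expect_true(all(abs(bpFit - tab$bp[ok]) < 3 * se + 0.02))
})

test_that("Newick export carries AU|BP labels and parses with ape", {
  set.seed(9)
  m <- twoBlockMatrix(60, 8, 0.8)
  cs <- pvcluster(m, nBoot = 120, seed = 5)
  path <- tempfile(fileext = ".nwk")
  exportNewick(cs, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, colnames(m))
  expect_equal(tr$Nnode, ncol(m) - 1)
  expect_true(all(grepl("^\\d+\\.\\d\\|\\d+\\.\\d$", tr$node.label)))
  # ultrametric: all root-to-tip distances equal
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-8)
  tsv <- tempfile(fileext = ".tsv")
  exportSupportTable(cs, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), ncol(m) - 1)
  expect_true(all(c("node", "leaves", "au", "bp", "v", "c") %in% names(tab)))
})

test_that("doubling the bootstrap count leaves AU stable", {
  set.seed(10)
  m <- twoBlockMatrix(70, 10, 0.75)
  csA <- pvcluster(m, nBoot = 400, seed = 6)
  csB <- pvcluster(m, nBoot = 800, seed = 7)
  tab <- merge(csA@table, csB@table, by = "leaves")
  ok <- !tab$degenerate.x & !tab$degenerate.y
  expect_true(any(ok))
  # the v - c extrapolation amplifies per-scale binomial noise about
  # three-fold, so at 400/800 replicates the Monte-Carlo sd of AU is ~0.03;
  # differences stay within 4 sd
  expect_true(all(abs(tab$au.x[ok] - tab$au.y[ok]) < 0.12))
  # strongly supported nodes are rock-stable
  strong <- tab$au.x > 0.99
  expect_true(all(abs(tab$au.x[strong] - tab$au.y[strong]) < 0.01))
})
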