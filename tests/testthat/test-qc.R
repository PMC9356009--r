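test_that("half-LOD flooring follows the left-censoring rule", {
  expect_equal(floorToLOD(3, 10), 5)
  expect_equal(floorToLOD(12, 10), 12)
  expect_true(is.na(floorToLOD(NA, 10)))
  expect_equal(floorToLOD(10, 10), 10)  # at the limit: detected
  expect_equal(floorToLOD(c(3, 12, NA), 10), c(5, 12, NA))
  expect_error(floorToLOD(3, 0), "lod")
  x <- tinyExperiment(nChildren = 2, fill = 0.3, batch = c("1", "2"))
  xf <- floorExperiment(x)
  expect_equal(unname(assay(xf, "Media")[1, ]), c(0.4, 0.25))  # per-batch LODs
})

test_that("sample exclusions implement the viability and sentinel rules", {
  x <- tinyExperiment(nChildren = 5, fill = 100,
                      viability = c(4, 15, 15, 15, 90))
  # child 2: all sentinels low -> inadequate; child 3: one sentinel high
  for (i in seq_len(nrow(defaultQCThresholds()$sentinels))) {
    sn <- defaultQCThresholds()$sentinels[i, ]
    a <- assay(x, sn$stimulus)
    a[sn$cytokine, 2] <- sn$max_pg_ml - 1
    a[sn$cytokine, 3] <- sn$max_pg_ml - 1
    assay(x, sn$stimulus) <- a
  }
  a <- assay(x, "RV16"); a["IFNg", 3] <- 8; assay(x, "RV16") <- a
  res <- applySampleExclusions(x, excludeOther = c(c04 = "no response seen"))
  expect_equal(res$report$excluded_low_viability, "c01")
  expect_equal(res$report$excluded_inadequate, "c02")
  expect_equal(res$report$excluded_other, "c04", ignore_attr = TRUE)
  expect_setequal(res$report$retained, c("c03", "c05"))
  # the report partitions the children
  expect_setequal(unlist(res$report), children(x))
  expect_equal(children(res$experiment), c("c03", "c05"))
})

test_that("missing sentinel responses do not trigger the inadequate rule", {
  x <- tinyExperiment(nChildren = 1, viability = 15)
  for (s in stimuli(x)) {
    a <- assay(x, s); a[] <- 1; a[c("IP10", "MCP4"), 1] <- NA; assay(x, s) <- a
  }
  res <- applySampleExclusions(x)
  # all sentinel pairs present and low -> excluded
  expect_equal(res$report$excluded_inadequate, "c01")
  a <- assay(x, "PHA"); a["IL2", 1] <- NA; assay(x, "PHA") <- a
  res2 <- applySampleExclusions(x)
  expect_equal(res2$report$retained, "c01")
})

test_that("batch coefficients equal the log2 mean difference with batch 2 baseline", {
  x <- tinyExperiment(nChildren = 4, batch = c("1", "1", "2", "2"))
  a <- assay(x, "Hin"); a["IL6", ] <- c(4, 4, 8, 8); assay(x, "Hin") <- a
  bm <- estimateBatchModel(x)
  expect_equal(bm$coefficient[bm$cytokine == "IL6" & bm$stimulus == "Hin"], -1)
  # regression oracle: lm on a batch indicator gives identical coef and SE
  set.seed(4)
  y <- c(4, 4, 8, 8) * exp(rnorm(4, sd = 0.2))
  a["IL6", ] <- y; assay(x, "Hin") <- a
  bm <- estimateBatchModel(x)
  fit <- summary(stats::lm(log2(y) ~ factor(c("1", "1", "2", "2"),
                                            levels = c("2", "1"))))
  row <- bm[bm$cytokine == "IL6" & bm$stimulus == "Hin", ]
  expect_equal(row$coefficient, unname(fit$coefficients[2, 1]), tolerance = 1e-12)
  expect_equal(row$se, unname(fit$coefficients[2, 2]), tolerance = 1e-12)
})

test_that("null batch coefficients stay inside 3 SE and a planted shift is recovered", {
  # identical batch distributions: |coef| < 3 SE in ~99% of simulations
  set.seed(11)
  inside <- vapply(1:1000, function(i) {
    y1 <- rnorm(20); y2 <- rnorm(60)
    coef <- mean(y1) - mean(y2)
    sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / 78
    abs(coef) < 3 * sqrt(sp2 * (1 / 20 + 1 / 60))
  }, logical(1))
  expect_gt(mean(inside), 0.985)

  # planted -0.7 shift at n = 300 with small residual noise
  set.seed(12)
  x <- tinyExperiment(nChildren = 300,
                      batch = rep(c("1", "2"), c(150, 150)))
  a <- assay(x, "LPS")
  a["TNF", ] <- 2^(5 + rnorm(300, sd = 0.1) - 0.7 * rep(c(1, 0), c(150, 150)))
  assay(x, "LPS") <- a
  bm <- estimateBatchModel(x)
  expect_lt(abs(bm$coefficient[bm$cytokine == "TNF" &
                                 bm$stimulus == "LPS"] + 0.7), 0.05)
})

test_that("batch adjustment subtracts on log2 scale, refloors, and leaves batch 2 intact", {
  x <- tinyExperiment(nChildren = 4, batch = c("1", "1", "2", "2"))
  a <- assay(x, "Hin"); a["IL6", ] <- c(4, 4, 8, 8); assay(x, "Hin") <- a
  a2 <- assay(x, "LPS"); a2["IL6", ] <- c(0.9, 16, 1, 1); assay(x, "LPS") <- a2
  bm <- estimateBatchModel(x)
  before <- assay(x, "Hin")[, 3:4]
  adj <- adjustBatch(x, bm)
  # coefficient -1: batch-1 values 4 -> 8
  expect_equal(unname(assay(adj, "Hin")["IL6", 1:2]), c(8, 8))
  expect_identical(assay(adj, "Hin")[, 3:4], before)
  # LPS: batch 1 higher on average, so the small batch-1 value drops
  co <- bm$coefficient[bm$cytokine == "IL6" & bm$stimulus == "LPS"]
  expect_lt(2^(log2(0.9) - co), 0.5)  # falls below the batch-2 LOD ...
  expect_equal(unname(assay(adj, "LPS")["IL6", 1]), 0.25)  # ... so half-LOD
  expect_equal(unname(assay(adj, "LPS")["IL6", 2]), 2^(4 - co))
})

test_that("re-estimated batch coefficients vanish after adjustment", {
  coh <- generateCohort(simConfig(n_children = 120,
                                  batch_sizes = c(40L, 80L), seed = 8,
                                  n_null_snps = 0L, apply_missingness = FALSE))
  x <- floorExperiment(coh$experiment)
  bm <- estimateBatchModel(x)
  adj <- adjustBatch(x, bm)
  bm2 <- estimateBatchModel(adj)
  # wherever no re-flooring occurred the re-fit coefficient is ~0
  checked <- 0L
  for (s in c("Hin", "RV16", "PHA")) {
    floorHits <- rowSums(assay(adj, s)[, childBatch(adj) == "1"] ==
                           lodOf(adj, "2") / 2, na.rm = TRUE)
    clean <- names(floorHits)[floorHits == 0]
    sub <- bm2[bm2$stimulus == s & bm2$cytokine %in% clean, ]
    checked <- checked + nrow(sub)
    expect_true(all(abs(sub$coefficient) < 1e-10, na.rm = TRUE))
  }
  expect_gt(checked, 10)
})

test_that("media normalisation is the log2 difference against the media well", {
  x <- tinyExperiment(nChildren = 2)
  a <- assay(x, "Media"); a["IL6", ] <- c(10, 10); assay(x, "Media") <- a
  a <- assay(x, "Hin"); a["IL6", ] <- c(80, 10); assay(x, "Hin") <- a
  a <- assay(x, "LPS"); a["IL6", ] <- c(NA, 0.25); assay(x, "LPS") <- a
  folds <- mediaNormalize(x)
  m <- assay(folds, "log2fold")
  expect_equal(unname(m["IL6.Hin", ]), c(3, 0))
  expect_true(is.na(m["IL6.LPS", 1]))
  # censored pairs at the common half-LOD floor carry no induction signal
  a <- assay(x, "Media"); a["IL8", ] <- 0.25; assay(x, "Media") <- a
  a <- assay(x, "Fla"); a["IL8", ] <- 0.25; assay(x, "Fla") <- a
  m <- assay(mediaNormalize(x), "log2fold")
  expect_equal(unname(m["IL8.Fla", ]), c(0, 0))
  # media never appears as a pair
  expect_false("Media" %in% rowData(folds)$stimulus)
  expect_equal(nrow(folds), 28 * 15)
})

test_that("flooring and normalisation are idempotent", {
  coh <- generateCohort(simConfig(n_children = 40,
                                  batch_sizes = c(10L, 30L), seed = 3,
                                  n_null_snps = 0L))
  x1 <- floorExperiment(coh$experiment)
  x2 <- floorExperiment(x1)
  expect_identical(assays(x1), assays(x2))
  f1 <- mediaNormalize(x1)
  f2 <- mediaNormalize(x1)
  expect_identical(assay(f1, "log2fold"), assay(f2, "log2fold"))
})

test_that("Bonferroni alpha divides 0.05 by the pair count", {
  expect_equal(bonferroniAlpha(28, 15), 0.05 / 420)
  expect_equal(signif(bonferroniAlpha(28, 15), 3), 1.19e-4)
  expect_equal(bonferroniAlpha(1, 1), 0.05)
  expect_equal(bonferroniAlpha(2, 5), 0.005)
  expect_error(bonferroniAlpha(0, 5))
})

test_that("induction test matches the one-sided t oracle", {
  m <- cbind(p1 = c(1, 1, 2), p2 = c(0, 0, 0), p3 = c(5, 5, 5))
  rownames(m) <- c("a", "b", "c")
  res <- testInduction(m, alpha = 0.05)
  # hand computation: mean 4/3, sd 1/sqrt(3), t = 4
  expect_equal(res$t[1], 4, tolerance = 1e-12)
  expect_equal(res$p[1], stats::pt(4, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p[1], 3), 0.029)
  # independent oracle: t.test one-sided
  tt <- stats::t.test(m[, 1], alternative = "greater")
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-10)
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-10)
  # all-zero folds: mean fold 1, untestable (zero variance)
  expect_equal(res$mean_fold[2], 1)
  expect_true(res$untestable[2])
  expect_false(isTRUE(res$significant[2]))
  expect_true(res$untestable[3])
  expect_equal(res$mean_fold[3], 32)
})

test_that("viability diagnostics recover planted associations", {
  set.seed(9)
  n <- 300
  v <- pmin(pmax(100 * rbeta(n, 8, 1.5), 1), 100)
  x <- tinyExperiment(nChildren = n, viability = v,
                      batch = rep(c("1", "2"), c(100, 200)))
  # plant r ~ 0.25 between the IL16/Strpn response and viability
  a <- assay(x, "Strpn")
  vs <- scale(v)[, 1]
  a["IL16", ] <- 50 + 10 * (0.25 * vs + sqrt(1 - 0.25^2) * rnorm(n))
  assay(x, "Strpn") <- a
  # and a perfect copy
  a["IL18", ] <- v
  assay(x, "Strpn") <- a
  d <- viabilityDiagnostics(x)
  rv <- d$response_viability
  expect_equal(rv$r[rv$cytokine == "IL18" & rv$stimulus == "Strpn"], 1)
  expect_lt(abs(rv$r[rv$cytokine == "IL16" & rv$stimulus == "Strpn"] - 0.25),
            0.1)
  expect_gt(d$batch_p, 0.001)  # viability independent of batch here
})
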