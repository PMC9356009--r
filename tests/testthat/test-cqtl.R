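test_that("exact HWE test matches brute-force enumeration", {
  expect_equal(hweExact(25, 50, 25), 1)
  expect_equal(hweExact(10, 0, 0), 1)   # monomorphic
  expect_equal(hweExact(0, 0, 10), 1)
  expect_equal(hweExact(5, 0, 5), hweEnumerate(5, 0, 5), tolerance = 1e-12)
  expect_error(hweExact(-1, 2, 3), "negative")
  # exhaustive agreement for all configurations up to 50 diploids
  set.seed(1)
  for (rep in 1:150) {
    n <- sample(2:50, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExact(nAA, nAa, naa), hweEnumerate(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
  # strong HWE violation is detected
  expect_lt(hweExact(50, 0, 50), 1e-20)
})

test_that("SNP QC applies the typed and imputed stage filters", {
  dos <- matrix(rep(c(0, 1, 2, 1), 25), nrow = 5, ncol = 20,
                dimnames = list(paste0("s", 1:5), paste0("c", 1:20)))
  info <- data.frame(
    chrom = 1, pos = 1:5, ref = "A", alt = "G",
    typed = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    call_rate = c(0.99, 0.90, 1, 1, 1),
    info = c(1, 1, 0.70, 0.80, 0.9),
    maf = c(0.2, 0.2, 0.2, 0.04, 0.3),
    hwe_p = c(1e-3, 1, 1, 1, 1))
  gs <- GenotypeSet(dos, info)
  q1 <- snpQC(gs, "typed")
  expect_equal(q1$removed$snp, "s2")
  expect_equal(q1$removed$reason, "call_rate")
  expect_true("s1" %in% rownames(q1$genotypes))  # HWE 1e-3 passes 5.9e-7
  q2 <- snpQC(q1$genotypes, "imputed")
  expect_setequal(q2$removed$snp, c("s3", "s4"))
  expect_equal(q2$removed$reason[q2$removed$snp == "s3"], "info")
  expect_equal(q2$removed$reason[q2$removed$snp == "s4"], "maf")
  expect_setequal(rownames(q2$genotypes), c("s1", "s5"))
  # a typed SNP violating HWE hard is removed with reason hwe
  info2 <- info; info2$hwe_p[1] <- 1e-8; info2$call_rate[2] <- 1
  q3 <- snpQC(GenotypeSet(dos, info2), "typed")
  expect_equal(q3$removed$reason, "hwe")
})

test_that("KS normality screen is conservative under the null and powerful", {
  set.seed(2)
  # parameters are estimated from the sample, so the classical KS p is
  # conservative (super-uniform); it must not over-reject
  pNull <- vapply(1:200, function(i) ksNormality(rnorm(200)), numeric(1))
  expect_lt(mean(pNull < 0.05), 0.03)
  expect_gt(mean(pNull), 0.5)
  # exponential data at n = 300 is flagged essentially always
  pExp <- vapply(1:100, function(i) ksNormality(rexp(300)), numeric(1))
  expect_gte(mean(pExp < 0.01), 0.99)
  expect_error(ksNormality(rep(1, 50)), "degenerate")
  expect_error(ksNormality(rnorm(5)), "at least 10")
})

test_that("additive score test equals closed-form least squares on toy data", {
  res <- scoreTestAdditive(c(0, 1, 2, 3), c(0, 1, 1, 2), minN = 2)
  expect_equal(res$beta, 1.5)
  # brute-force OLS oracle
  set.seed(3)
  y <- rnorm(200); g <- rbinom(200, 2, 0.25)
  st <- scoreTestAdditive(y, g)
  ols <- summary(stats::lm(y ~ g))$coefficients
  expect_lt(abs(st$beta - ols[2, 1]), 1e-10)
  # score and Wald p agree asymptotically
  set.seed(4)
  yb <- rnorm(10000); gb <- rbinom(10000, 2, 0.25)
  stb <- scoreTestAdditive(yb, gb)
  olsb <- summary(stats::lm(yb ~ gb))$coefficients
  expect_lt(abs(stb$p / olsb[2, 4] - 1), 0.01)
  # degenerate dosage flagged, not raised
  flat <- scoreTestAdditive(y, rep(1, 200))
  expect_true(is.na(flat$p))
})

test_that("complete-case handling: children with missing data change nothing", {
  set.seed(5)
  y <- rnorm(100); g <- rbinom(100, 2, 0.3)
  base <- scoreTestAdditive(y, g)
  expect_identical(scoreTestAdditive(c(y, NA), c(g, 2)), base)
  expect_identical(scoreTestAdditive(c(y, 1.5), c(g, NA)), base)
  bin <- scoreTestBinary(y > 0, g)
  expect_identical(scoreTestBinary(c(y > 0, NA), c(g, 1)), bin)
})

test_that("binary score test recovers planted log-odds and rejects degenerate input", {
  set.seed(6)
  est <- vapply(1:30, function(i) {
    g <- rbinom(2000, 2, 0.3)
    y <- runif(2000) < stats::plogis(stats::qlogis(0.18) + 0.6 * g)
    scoreTestBinary(y, g)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.15)
  expect_error(scoreTestBinary(rep(FALSE, 50), rbinom(50, 2, 0.3)),
               "both classes")
})

test_that("genome scan flags planted cQTLs and respects the threshold", {
  coh <- generateCohort(simConfig(n_children = 200,
                                  batch_sizes = c(40L, 160L), seed = 9,
                                  n_null_snps = 300L))
  x <- applySampleExclusions(floorExperiment(coh$experiment))$experiment
  folds <- mediaNormalize(adjustBatch(x, estimateBatchModel(x)))
  q <- snpQC(snpQC(coh$genotypes, "typed")$genotypes, "imputed")$genotypes
  traits <- data.frame(cytokine = "IL6", stimulus = c("Hin", "LPS"))
  scan <- genomeScan(folds, q, traits)
  expect_true(all(diff(scan$p) >= 0, na.rm = TRUE))  # sorted by p
  # the strongest planted IL-6 effects dominate the top of the scan
  top <- scan$snp[1:6]
  expect_gt(sum(grepl("^rs_il6_", top)), 3)
  # threshold = 1 flags every tested SNP
  all1 <- genomeScan(folds, q, traits, threshold = 1)
  expect_true(all(all1$significant[!is.na(all1$p)]))
  # permuted trait: nothing reaches genome-wide significance
  set.seed(10)
  fp <- folds
  mm <- assay(fp, "log2fold")[, sample(ncol(fp))]
  colnames(mm) <- colnames(fp)
  SummarizedExperiment::assay(fp, "log2fold", withDimnames = FALSE) <- mm
  scanP <- genomeScan(fp, q, traits)
  expect_equal(sum(scanP$significant), 0)
  expect_error(genomeScan(folds, q, traits[0, ]), "empty trait list")
  expect_error(genomeScan(folds, q, data.frame(cytokine = "IL6",
                                               stimulus = "NotThere")),
               "not present")
})

test_that("specificity profile is strongest for the causal pair group", {
  coh <- generateCohort(simConfig(n_children = 250,
                                  batch_sizes = c(50L, 200L), seed = 11,
                                  n_null_snps = 10L))
  x <- applySampleExclusions(floorExperiment(coh$experiment))$experiment
  folds <- mediaNormalize(adjustBatch(x, estimateBatchModel(x)))
  prof <- specificityProfile("rs_il6_f", folds, coh$genotypes,
                             defaultSpecificityGroups("Fla"))
  expect_equal(prof$summary$n_pairs, c(7, 4, 56, 16, 7, 4))
  hitRate <- prof$summary$n_nominal / prof$summary$n_pairs
  # IL-6/bacterial group leads; cross-group rates are lower
  expect_equal(which.max(hitRate), 1L)
  # null SNP: roughly nominal-level hits
  prof0 <- specificityProfile("rs_null_0005", folds, coh$genotypes)
  expect_lt(sum(prof0$summary$n_nominal) / sum(prof0$summary$n_pairs), 0.25)
  expect_error(specificityProfile("rs_il6_f", folds, coh$genotypes,
                                  list(empty = data.frame())), "empty group")
})

test_that("phenotype association links the planted cQTL to its outcome", {
  pv <- vapply(1:6, function(s) {
    coh <- generateCohort(simConfig(n_children = 800,
                                    batch_sizes = c(100L, 700L), seed = s,
                                    n_null_snps = 0L))
    pa <- phenotypeAssociation(c("rs_il6_f", "rs_av_a"), coh$genotypes,
                               coh$clinical$records)
    c(pa$p[pa$snp == "rs_il6_f" & pa$trait == "gina_step2"],
      pa$p[pa$snp == "rs_av_a" & pa$trait == "gina_step2"])
  }, numeric(2))
  # the linked SNP (log-OR 0.73) associates far more often than an unlinked one
  expect_gt(sum(pv[1, ] < 0.05), sum(pv[2, ] < 0.05))
  expect_gte(sum(pv[1, ] < 0.05), 4)
})
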