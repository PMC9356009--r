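# Small in-code fixtures shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A tiny CytokineExperiment with hand-chosen concentrations: nChildren
# children, the default 28-cytokine panel, all 16 stimuli, constant fill
# value unless overridden afterwards.
tinyExperiment <- function(nChildren = 4, fill = 100,
                           batch = rep("2", nChildren),
                           viability = rep(90, nChildren)) {
  sp <- defaultStimulusPanel()
  cp <- defaultCytokinePanel()
  kids <- sprintf("c%02d", seq_len(nChildren))
  assaysL <- lapply(stats::setNames(sp$stimulus, sp$stimulus), function(s)
    matrix(fill, nrow(cp), nChildren, dimnames = list(cp$cytokine, kids)))
  CytokineExperiment(assaysL, batch, viability, sp, cp)
}

# Deterministic (noise-free) simulation config: no reactivity, no genetic
# effects, no batch shift, no missingness -- every stimulated response
# equals its media response.
nullSimConfig <- function(n = 10, seed = 1) {
  sp <- defaultStimulusPanel()
  cp <- defaultCytokinePanel()
  m <- defaultSignatureModel(sp, cp)
  m$signature[] <- 0
  m$batch_shift[] <- 0
  m$child_reactivity_sd[] <- 0
  m$noise_sd <- 0
  m$genetic_effects <- m$genetic_effects[0, ]
  m$phenotype_links <- m$phenotype_links[0, ]
  m$inadequate_rate <- 0
  m$low_viability_rate <- 0
  simConfig(n_children = n, batch_sizes = c(max(1, n %/% 4), n - max(1, n %/% 4)),
            seed = seed, stimulusPanel = sp, cytokinePanel = cp, model = m,
            n_null_snps = 0L, apply_missingness = FALSE)
}

# Two-block column structure: nCol columns in two equal blocks with
# within-block correlation about r, independent blocks.
twoBlockMatrix <- function(n = 100, nCol = 20, r = 0.9) {
  b <- nCol / 2
  z1 <- rnorm(n); z2 <- rnorm(n)
  s <- sqrt(r); e <- sqrt(1 - r)
  m <- cbind(matrix(s * z1, n, b) + e * matrix(rnorm(n * b), n, b),
             matrix(s * z2, n, b) + e * matrix(rnorm(n * b), n, b))
  colnames(m) <- sprintf("v%02d", seq_len(nCol))
  rownames(m) <- sprintf("r%03d", seq_len(n))
  m
}

# Brute-force exact HWE p-value by direct enumeration of all genotype
# configurations with the observed allele counts (independent of the
# log-space implementation under test).
hweEnumerate <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    n1 <- (min(nA, na) - h) / 2    # rare homozygotes
    n2 <- (max(nA, na) - h) / 2    # common homozygotes
    exp(lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  })
  prob <- prob / sum(prob)  # guard accumulated rounding
  obs <- prob[hets == nAa]
  sum(prob[prob <= obs * (1 + 1e-12)])
}
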