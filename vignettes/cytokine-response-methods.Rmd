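---
title: "Profiling PBMC cytokine responses: models and methods"
author: "cytoResponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling PBMC cytokine responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

`cytoResponse` analyses population-scale profiles of stimulated peripheral
blood mononuclear cell (PBMC) cytokine secretion. The data are a
three-way array: for each child in a birth cohort, supernatant
concentrations (pg/mL) of a multiplex cytokine panel are measured after
24 h culture with a battery of stimuli — live respiratory viruses and
bacteria, Toll-like receptor ligands, the T-cell mitogen PHA, and an
unstimulated media control. The package asks three questions of such data:

1. **Architecture** — do stimuli and cytokines organise into reproducible
   groups (viral vs bacterial vs T-cell; anti-viral vs pro-inflammatory vs
   T-cell-derived cytokines)?
2. **Between-child variation** — how large are the child-to-child
   differences in induction, and are they structured (correlated within
   functional groups)?
3. **Genetics and clinic** — are there cytokine quantitative trait loci
   (cQTLs) for strongly induced responses such as IL-6 after bacterial
   stimulation, and do they associate with asthma-related outcomes?

Because participant-level cohort data of this kind are access-controlled,
the package ships a synthetic-cohort generator that emulates the
statistical structure such a study produces. Every analysis stage is
exercised end to end on generated cohorts; the generator is first-class,
tested code, not a test fixture.

# Data containers

* `CytokineExperiment` — a `SummarizedExperiment` with one assay per
  stimulus (cytokine x child, pg/mL, `NA` = not measured), per-child batch
  and viability in `colData`, per-cytokine functional group and per-batch
  detection limits in `rowData`.
* `FoldMatrix` — media-normalised log2 fold inductions, one row per
  (cytokine, stimulus) pair; optionally an `imputed` indicator assay.
* `GenotypeSet` — SNP x child minor-allele dosages with per-SNP quality
  metrics (call rate, imputation info score, MAF, exact HWE p).
* `UnfoldedView`, `PCAResult`, `PPCAModel`, `ClusterSupport` — the derived
  objects of the unfolding/PCA, imputation and clustering stages.

# Preprocessing model

**Left-censoring.** Immunoassay readings below the per-cytokine, per-batch
lower detection limit (LOD) are stored as half the LOD (`floorToLOD`).
This is a convention, not an estimate: censored cells carry no induction
signal, and a stimulated/media pair that are both censored yields a fold
induction of exactly one.

**Sample QC.** Children are excluded outright below 5% viability, and as
"inadequate responders" when viability is below 20% *and* four sentinel
responses (IL-2/PHA, IFN-a2/RSV, IFN-g/RV16, IL-6/Hin) are all below their
pg/mL cutoffs. The conjunction is deliberate: any healthy sentinel rescues
the sample. A missing sentinel cannot demonstrate an absent response, so
it fails the conjunction and the child is retained. All thresholds are
configuration (`defaultQCThresholds()`), not constants.

**Batch adjustment.** Two shipment batches were assayed years apart, and
the assay shift is multiplicative in concentration, hence additive in
log2. Per (cytokine, stimulus) pair — media included, because the shift is
an assay property, not a biology property — the batch-1 offset is the
fitted coefficient of a regression of log2 concentration on a batch
indicator with the larger batch 2 as baseline, which for a single binary
covariate equals the difference of batch means. The coefficient is
subtracted from batch-1 log2 values; batch-2 values are left bit-identical.
Adjusted concentrations falling below the batch-2 LOD are re-floored to
half that LOD, keeping the censoring convention coherent after adjustment.
A pair observed in fewer than two children in either batch passes through
unadjusted with a warning. No covariates beyond the batch indicator enter
the model; the adjustment operates on log2 values throughout because every
downstream analysis is log-scale.

**Media normalisation.** The analysis quantity is
`log2(stimulated) - log2(media)` per child and cytokine; the media well is
consumed as the reference and never appears as a trait.

**Induction testing.** Each pair is tested with a one-sample, right
one-sided t-test of mean log2 fold > 0 at the Bonferroni level
`0.05 / (n_cytokines * n_stimuli)` (about 1.19e-4 for a 28 x 15 panel).
The reported "mean fold induction" is the back-transformed mean of log2
folds — a geometric mean — because the test is defined on the log scale.
Pairs with fewer than two observations or zero variance are flagged
untestable rather than significant.

# PPCA imputation

Missing responses arise mostly by design: when too few cells are
recovered, stimuli are cultured in a fixed priority order, so a child is
missing exactly the lowest-priority stimuli. Imputation uses probabilistic
PCA — the latent Gaussian factor model `x = W z + mu + eps` with isotropic
noise — fitted by EM on the **observed-data likelihood**: missing entries
are marginalised, so each child contributes a Gaussian over its observed
pairs only. This choice (rather than treating missing cells as latent
data) gives the clean guarantee that the observed-data log-likelihood is
non-decreasing over iterations, which the test suite asserts at every
step. The E/M updates run in compiled code (RcppArmadillo); per-feature
`(mu_j, W_j)` updates solve small `(k+1) x (k+1)` systems over the
children observing feature j, and `sigma^2` is updated in closed form.

*Initialisation*: observed column means for `mu`, the SVD of the
mean-filled matrix for `W`, residual variance for `sigma^2`; restarts
perturb that start, and the best final likelihood is kept
(deterministic given the seed). *Convergence*: relative log-likelihood
change below 1e-6, at most 1000 iterations.

*Dimensionality* is selected by Bayesian model selection: Minka's Laplace
approximation to the log model evidence, computed from the eigenvalues of
the sample covariance (of the mean-filled matrix when incomplete),
maximised over candidates; the full evidence curve is kept for audit.

*Which matrix is imputed*: the child x (cytokine, stimulus) fold matrix.
Media wells are never imputed — they are the reference, already consumed
by normalisation. Whether one should impute raw log2 concentrations
instead is not decidable from first principles; the fold matrix is the
clustering input, so imputing it directly is the choice made here, and
both paths can be built from the exported functions if a sensitivity
analysis is wanted. Children with no observed pair at all carry no
evidence and are imputed to the mean.

*Validation* (`validateImputation`) masks a fresh random subset of
observed cells at the study's missing rate, imputes by PPCA and by
per-feature means, and compares RMSE on the identical masked cells. On
correlated data PPCA wins essentially always; on pure noise the two are
equivalent to within the small overfitting penalty of PPCA's spurious
component (a systematic but negligible effect — a paired test will detect
it at any replicate count, which is why the tests assert effect-size
equivalence rather than statistical indistinguishability).

# Unfoldings, PCA, correlations

Three matrix unfoldings of the fold tensor are provided: child-stimulus
rows x cytokine columns (to cluster cytokines), child-cytokine rows x
stimulus columns (to cluster stimuli), and child rows x pair columns (for
child-level substructure). Unfolding is a bijection on the retained cells;
the tests verify value-multiset preservation and exact refolding. An
exclusion list removes stimuli from all views; it defaults to polyIC,
reflecting the contamination history of that reagent in the motivating
study, and is configuration rather than hard-coded.

PCA is a column-centred SVD. Columns are *not* standardised by default —
all values already share the log2 fold scale, and standardisation would
up-weight weakly induced pairs; a flag enables it so both conventions are
computable. Pairwise Pearson correlations use pairwise-complete
observations with p-values from the t transform; zero-variance columns
yield flagged `NA`s.

# Multiscale bootstrap cluster support

Stimuli and cytokines are clustered with correlation distance
(`1 - Pearson`) and average linkage (UPGMA, via `stats::hclust`; the merge
sequence is deterministic for a given distance matrix). Cluster
reliability uses the multiscale bootstrap:

* For each scale `r` in {0.5, ..., 1.4}, resample `ceiling(r * n)` of the
  n rows with replacement, recluster, and record for each observed node
  the fraction of replicates containing the identical leaf set — the
  per-scale bootstrap probability BP. 1000 replicates per scale is the
  default (the per-scale convention of the standard implementation of
  this method).
* Transform to `z(tau) = qnorm(1 - BP)` with `tau = sqrt(n / n')` and fit
  the signed-distance/curvature model `z = v * tau + c / tau` by weighted
  least squares with binomial weights `nBoot * dnorm(z)^2 / (BP (1 - BP))`.
  WLS is first-order equivalent to the maximum-likelihood fit and easier
  to verify against an oracle; the weighted residual sum of squares is
  exposed (`fit_rss`) to catch poor fits.
* The approximately unbiased probability is `AU = 1 - pnorm(v - c)`; the
  fitted ordinary BP at `tau = 1` is `1 - pnorm(v + c)`, so a
  zero-curvature fit collapses AU onto BP. AU > 0.95 marks a node highly
  supported.

Numerical details: per-scale frequencies are clipped to
`[1/(nBoot+1), 1 - 1/(nBoot+1)]` before the probit transform; curves that
are all 0 or all 1 are degenerate (AU 0 or 1, flagged, no fit); fewer than
three usable scales yields a flagged `NA`. Cluster identity across
replicates is exact leaf-set equality — the definition of BP — with no
topology-aware matching. A replicate in which a column is constant (so a
correlation is undefined) treats that column as uncorrelated. The
replicate stream is one seeded RNG sequence (scales in order, `nBoot`
index draws each), so the tests re-derive BP at scale 1 with an
independently coded loop and match it exactly.

Alternative linkages and distances are available through `hclust`
arguments on the exported distance matrix for stability checks, but are
not analysed further.

# cQTL mapping

SNP QC mirrors standard GWAS practice: genotyped SNPs require call rate
>= 0.95, exact Hardy-Weinberg p > 5.9e-7 and MAF > 0.005; imputed SNPs
require info score >= 0.75 and MAF >= 0.05. The HWE test is the exact
conditional test (enumeration over heterozygote counts in log space) —
correct at the low genotype counts that small simulations produce, where
the chi-square approximation is not.

Association uses the classical additive-model score test:
`U = sum((g - mean(g))(y - mean(y)))`, `V = s0^2 * sum((g - mean(g))^2)`
with `s0^2` the null maximum-likelihood residual variance, and
`U^2 / V ~ chi^2_1`. The reported beta is the least-squares slope. Binary
clinical phenotypes use the logistic score test with the analogous null
variance and a one-step log-odds estimate. Dosages are oriented to the
minor allele so effect signs are comparable to the convention "alleles
associated with lower IL-6 release". No covariates enter the tests (none
are defined for the synthetic cohorts); complete cases only — no
imputation ever feeds the cQTL analysis. The score method of dedicated
GWAS software additionally models dosage uncertainty under missingness;
the classical test implemented here coincides with it for hard or
complete dosages and is the documented divergence otherwise.

The genome scan runs each requested (cytokine, stimulus) trait against
every SNP (vectorised), sorts by p and flags `P < 5e-8`. Specificity
profiling tests one SNP against six predefined pair groups — IL-6 x other
bacterial stimuli (7), IL-6 x viral stimuli (4), other pro-inflammatory
cytokines x bacterial stimuli (56), virus-induced cytokines x viral
stimuli (16), and the two PHA groups (7, 4) — at nominal 0.05 with no
multiplicity correction, reporting per-group hit counts. Group membership
is configuration: in particular, which four of the five viral stimuli
constitute the "viral" group is not derivable from first principles, and
the default uses the four whose responses are most strongly mutually
correlated (RSV, RV16, R848, CpGA).

The Kolmogorov-Smirnov normality screen standardises the trait by its
sample mean and SD and tests against the standard normal. Because the
parameters are estimated from the same sample, the classical KS p-value is
conservative (the Lilliefors effect): under the null it is super-uniform,
never anti-conservative. The screen is therefore a safe gate — it
under-flags, not over-flags — and the tests assert exactly that behaviour.

# The synthetic cohort generator

`generateCohort()` draws, under one seed: viability (a Beta(8, 1.5) bulk
scaled to percent, with configured fractions of hard-failure and
"anergic" children), one reactivity scalar per functional group per child,
genotypes in Hardy-Weinberg proportions, clinical phenotypes, and the
response tensor

```
log2 conc(c, k, s) = baseline(k) + delta(k, s)
                   + a[c, group(k)] * 1[s != media]
                   + shift(k, s) * 1[batch(c) = 1]
                   + sum(beta * dosage(c))          (matching effects)
                   + eps,   eps ~ N(0, noise_sd^2)
```

followed by per-batch half-LOD censoring (censoring after the batch shift,
matching assay physics — measurement happens per batch) and the
rank-monotone missingness mask.

Key default choices, each encoding a condition of the study design the
generator emulates:

* **Panels.** 16 culture conditions (media + 15 stimuli) in culture-rank
  order with per-stimulus target missing rates taken from the study's
  design table. Two adjustments keep the targets compatible with the
  count-based monotone mechanism: the one adjacent non-monotone pair of
  printed rates (CpG-A/PAM) is pooled to its mean, and polyIC — whose
  observed rate is unreported — is interpolated from its rank neighbours
  (9.6%). The mean target over stimulated pairs is then ~18.9%, matching
  the study's reported ~18% overall missingness. The 28-cytokine panel
  covers the 26 analytes the study names; two low-level analytes (IL-7,
  IL-33) complete the plex as a synthetic default and sit in the
  weak/not-induced group.
* **Signature.** Mean log2 fold inductions are set from the published
  response landscape: IFN-a2 ~1000-fold under live viruses, IL-6 up to
  280-fold under bacteria (geometric mean), IL-17 67-fold under PHA,
  IFN-g strong under viruses, Hin and LPS, weak under Gram-positive
  ligands, and so on. polyIC is given a clean, moderate viral profile (the
  generator does not model reagent contamination). Because genetic effects
  enter as `beta * dosage` (uncentred, as the model states), the default
  signature is stated *net of the mean genetic contribution*, so
  cohort-level geometric-mean folds equal their targets.
* **Reactivity and noise.** One reactivity scalar per functional group per
  child is the simplest structure that reproduces both the >1000-fold
  between-child ranges and the strong (r ~ 0.95) correlations between
  same-group pairs; SDs are 2.8 (anti-viral), 2.0 (pro-inflammatory),
  1.5 (T-cell), 0.5 (weak) log2 units. The residual SD 0.605 is calibrated
  jointly with the reactivity and genetic variances so the child-level
  IL-6 LPS~Hin correlation is 0.95. A limitation follows from this
  simplicity: the shared "size" component is stronger than in real data,
  so the 2-component Child-Cytokine PCA explains ~90% of synthetic
  variance where the real study reports 76%. Passing tests therefore
  demonstrate recovery of the planted structure, not calibration of PCA
  variance fractions to real cohorts.
* **Batch.** -0.7 log2 shift on batch 1 (the smaller, earlier batch tends
  to read lower), batch sizes 54 + 286, batch-1 LODs slightly higher
  (0.8 vs 0.5 pg/mL).
* **Genetics.** Six IL-6/bacterial cQTLs at published effect scales
  (betas -1.26 to -1.88 log2 per allele, MAF 0.10) plus fourteen causal
  SNPs on other trait groups and 2000 null SNPs by default; dosages in
  Hardy-Weinberg proportions. Two of the IL-6 cQTLs carry clinical
  phenotype links (log-odds 0.32-0.73 per allele) against an 18% baseline
  prevalence; the logistic intercept targets that prevalence in
  non-carriers, so the marginal prevalence is slightly above it.
* **Clinical records.** Medication histories are synthesised *consistent
  with* the drawn GINA case/control status: cases receive controller
  therapy whose class set maps back to the intended step under
  `deriveGinaStep`, controls at most as-needed SABA. GINA step
  classification itself is the stepwise rule set (step 5: OCS/anti-IgE;
  step 4: medium/high ICS + LABA or LTRA; step 3: low ICS + add-on,
  medium/high ICS alone, or combination inhaler; step 2: low ICS or LTRA;
  else step 1) and is monotone in the medication set.

What the generator does **not** emulate: assay plate layout, cell-type
composition, cryopreservation artefacts, reagent contamination, linkage
disequilibrium between SNPs, or non-monotone missingness. Conclusions
about those features cannot be drawn from passing tests.

# Problem sizes used by the test suite

Simulation sizes are chosen so the default suite completes comfortably on
one core while keeping every check at meaningful power: cohorts of 340
children (the full default) for structural recovery and statistics
recovery; 20 seeds at 250-1000 bootstrap replicates per scale for cluster
support; 100 replicates for the imputation comparison at the study's 18%
missing rate; 10^4 null simulations at n = 273 for score-test calibration;
and 20 seeds of 2000 children x 2001 SNPs for genome-wide power. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch at these sizes.

# Known limitations

* AU probabilities for mid-support nodes carry Monte-Carlo error roughly
  three times the per-scale binomial error (the v - c extrapolation has
  leverage); at 1000 replicates per scale this is ~0.015. Strongly
  supported nodes are unaffected.
* The Laplace evidence is computed on the mean-filled covariance when the
  matrix is incomplete; at the study's missing rates this biases the
  selected dimension at most mildly downward, and the imputation
  comparison is insensitive to k within +/- 2 of the optimum.
* The score test's null-variance estimate makes it exact only
  asymptotically; calibration is verified at the cohort's n rather than
  assumed.
* `hclust`'s tie-breaking is deterministic but implementation-defined;
  with continuous log2 fold data, exact distance ties essentially never
  occur.
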