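Package: cytoResponse
Title: Architecture of PBMC Cytokine Responses to Viral and Bacterial
    Stimuli
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale profiling of stimulated peripheral
    blood mononuclear cell (PBMC) cytokine responses. Implements sample and
    assay quality control with half-detection-limit left-censoring, two-batch
    regression adjustment, media normalisation and Bonferroni-corrected
    one-sided induction testing; probabilistic principal component analysis
    (PPCA) imputation of missing responses by expectation-maximisation with
    Laplace-evidence dimensionality selection; tensor unfoldings of the
    child-by-cytokine-by-stimulus response array with PCA; hierarchical
    clustering under correlation distance with multiscale-bootstrap
    approximately-unbiased (AU) cluster support; and additive-model score
    tests for cytokine quantitative trait loci (cQTL) and binary clinical
    phenotypes. A synthetic-cohort generator emulating the statistical
    structure of such studies makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: ImmunoOncology, Clustering, PrincipalComponent, SNP,
    QualityControl, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
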