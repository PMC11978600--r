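Package: cogtraj
Title: Cognitive Aging Trajectory Clustering and Multimodal Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-wave longitudinal cognitive
    aging cohorts. Generates seedable synthetic cohorts with four latent
    trajectory archetypes across cognitive, MRI volumetric, EEG, and
    risk-factor modalities; applies coverage, constancy, and interquartile
    range quality-control filters; summarizes multivariate cognitive
    batteries with a masked two-layer autoencoder tuned by ten-fold
    cross-validation; clusters variable-length trajectories with temporal
    k-means under multivariate dynamic time warping, selecting the number of
    clusters by the Davies-Bouldin index; extracts Z-scored steady-state
    visual evoked potential (SSVEP) power per scalp region via Welch
    spectra; compares biomarkers and risk factors across clusters with
    nonparametric tests; and validates cluster labels with per-modality
    logistic regression and ROC/AUC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    glmnet,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    readr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    mclust,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
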