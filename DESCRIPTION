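Package: oppstack
Title: Opportunistic Multimodal Stacking for Brain-Age Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer opportunistic stacking for predicting age (a surrogate
    health biomarker) from several high-dimensional feature blocks, for example
    MEG, fMRI and anatomical MRI derivatives. Layer one fits a ridge regression
    per block with the penalty tuned by generalized cross-validation; held-out
    linear age predictions are double-coded so that missing modalities become
    features, and a random-forest combiner learns from any subject with at
    least one observed block. Includes the M/EEG feature mathematics used as
    inputs (Welch spectra, alpha-peak frequency, 1/f slope, Hilbert envelopes,
    OAS-shrunk covariances with Riemannian tangent-space vectorization,
    orthogonalized envelope correlations, a minimum-norm source operator),
    model evaluation with paired fold-wise comparisons and chance baselines,
    permutation and impurity variable importance, partial dependence, and
    brain-age-delta associations with behavioral scores under three
    deconfounding specifications. A synthetic-data module generates multimodal
    datasets, behavioral scores and oscillatory signals with known ground
    truth so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
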