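Package: radarleak
Title: Demographic Leakage Analysis for Radar-Recorded Cardiac Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether contactless radar recordings of cardiac
    motion leak demographic attributes (sex, age group). Implements the full
    analysis chain: simulation of quadrature (I/Q) radar cohorts, ellipse-fit
    arctangent demodulation of chest displacement, MODWT multiresolution
    isolation of the heartbeat component, continuous-wavelet scalogram imaging,
    conditional Wasserstein GAN (gradient penalty) augmentation of scalogram
    training sets, convolutional frame classification with window-level hard
    voting, subject-wise evaluation with FAR/FRR metrics and Welch tests,
    Grad-CAM explanations, and temporal-aggregation privacy-threat curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
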