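Package: leafprice
Title: Near-Infrared Calibration of Fresh Tea Leaf Purchase Price
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for predicting the purchase
    price of graded fresh tea leaves from near-infrared diffuse-reflectance
    spectra. Provides a synthetic spectra generator with grade-linked
    quality-index chemistry and scatter artefacts; the classical
    pretreatment catalogue (SNV, MSC, Savitzky-Golay first and second
    derivatives, and their combinations); a NIPALS PLS1 engine with
    cross-validated model selection; synergy-interval PLS (si-PLS)
    exhaustive interval search; genetic-algorithm wavenumber selection;
    PCA compression with contribution rates; a 3-5-1 back-propagation
    neural network with saturating-linear, tanh and logistic transfer
    functions; and quality-index statistics (paired t-tests and pairwise
    linear fits among grade, quality index and price).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    mixOmics,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
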