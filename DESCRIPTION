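Package: flamlim
Title: Hybrid QSPR Models for Flammability Limits of Pure Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-property relationship (QSPR) models
    for the lower and upper flammability limits (LFL/UFL, volume percent) of
    pure compounds from precomputed molecular descriptors. The core estimator
    is a hybrid regression that combines multiple-linear, logarithmic and
    polynomial (descriptor-sum) term families, together with their
    interactions, into one design matrix fitted by minimum-norm least squares.
    Includes significance-based backward elimination of coefficients, the
    accuracy statistics customary in flammability QSPR work (ARD, AARD, AAE,
    sigma-squared, R-squared), two published compact predictor equations in
    the SIC0/AAC/PW5/GATS1v and MLOGP/Jhetv/PW5/SIC0/MATS4m descriptor sets,
    and a synthetic-data generator with known ground truth so the whole
    pipeline is testable without proprietary property databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
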