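Package: fermfuse
Title: Electronic Nose and Near-Infrared Data Fusion for Solid-State
    Fermentation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Non-invasive monitoring of solid-state fermentation stage from
    electronic-nose gas-sensor arrays and near-infrared reflectance spectra.
    Provides a seeded synthetic study generator emulating a multi-run
    fermentation trial, standard normal variate and maximum-response
    preprocessing, PCA feature extraction, feature-level fusion by
    fixed-point independent component analysis, and an AdaBoost ensemble of
    small backpropagation networks for fermentation-day identification,
    with leave-one-out cross-validation for component-count selection and
    run-based train/validation evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
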