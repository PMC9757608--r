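Package: abpanel
Title: Autoantibody Biomarker Panel Discovery and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for discovering and validating serum
    autoantibody panels for early cancer detection. Implements Yates
    continuity-corrected screening of clone reactivity counts, univariate
    Welch t screening of marker abundances, exhaustive subset search over
    candidate markers with ridge-stabilised binary logistic models under
    stratified k-fold cross-validation, panel-size saturation analysis,
    sensitivity-at-fixed-specificity and AUC metrics, principal-component
    visualisation, and independent test-set validation including combined
    models with conventional serum tumor markers. Ships a synthetic-data
    generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
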