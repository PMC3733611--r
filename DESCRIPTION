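Package: rocnest
Title: Added-Value Tests for New Biomarkers in Nested Classification Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for whether new biomarkers add predictive value
    to an existing panel in nested two-class classification models. Provides
    the exact F test of the ideal area under the ROC curve (AUC) for nested
    linear discriminant functions via sample Mahalanobis distances, likelihood
    ratio and Wald tests for nested logistic regression, and nonparametric
    comparison of two correlated AUCs on a common test set using either the
    DeLong structural-components variance estimator or an unbiased U-statistics
    variance estimator. A seeded Monte Carlo harness reproduces type I error
    and power tables for all tests and the resubstitution-versus-independent-
    test learning-curve ("antler") study, and a small command-line interface
    runs the tests on delimited score and biomarker files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
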