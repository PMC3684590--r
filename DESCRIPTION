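Package: dysconnect
Title: Whole-Brain Functional Connectivity Discrimination for Functional Dyspepsia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state functional-connectivity multivariate pattern analysis for
    case-control neuroimaging cohorts, built around functional dyspepsia. Conditions
    ROI time series (linear detrend, band-pass, nuisance regression), builds Fisher-z
    connectivity feature vectors, selects discriminative edges fold-wise with a
    permutation-calibrated two-sample t-test and a quality-of-life correlation filter,
    stabilizes them with an overlap threshold across leave-one-out folds, classifies
    subjects with a support-vector machine, predicts clinical scores by support-vector
    regression, derives a connectivity severity index, and characterizes the abnormal
    network (node weights, connection lengths, sign splits, cortical-system proportions).
    Includes a seeded synthetic-cohort generator with planted group and severity effects
    so the whole pipeline is testable without patient scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    pROC,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
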