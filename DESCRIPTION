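Package: audmix
Title: Latent-Cluster Regression for Longitudinal Audiogram Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares three regression predictors of hearing thresholds in
    longitudinal audiogram data -- pooled ordinary least squares, linear
    mixed-effects with patient-ear-frequency (PEF) random effects, and a
    grouped mixture of linear regressions fitted by EM under the constraint
    that all observations of a PEF share one latent cluster -- across three
    prediction tasks: missing-data imputation, future forecasting, and
    generalization to unseen patients via Bayes-rule cluster-membership
    inference without retraining.  Includes a synthetic cohort generator
    with known cluster structure, random effects, and within-individual
    drift, plus the inclusion/exclusion filtering and fold construction the
    task designs require.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
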