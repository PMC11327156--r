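Package: moodwatch
Title: Predicting Daily Mood from Continuous Wearable Neurophysiologic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for relating continuous 1 Hz neurophysiologic
    ("immersion") recordings to daily self-reported mood and energy. Detects
    statistically defined trough and peak events from per-person median/SD
    thresholds with minimum-duration run rules, short-gap interpolation and
    short-day exclusion; aggregates events into a participant-day feature
    table; fits fixed-effects least-squares models with day-clustered standard
    errors; and trains SMOTE-balanced classifiers (regularized logistic
    regression, support vector machines, random forests, gradient boosted
    trees) with cross-validated tuning, permutation feature importance and a
    resampling test against chance discrimination. Includes a calibrated
    synthetic cohort generator (mean-reverting baseline plus injected
    excursions) so the full pipeline is testable without access to any
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    data.table,
    yaml,
    jsonlite,
    sandwich,
    glmnet,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
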