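Package: gaitage
Title: Age Prediction from Trunk IMU Recordings of the Timed Up and Go and
    Six-Minute Walk Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating the age of elderly adults
    from a single trunk-worn inertial measurement unit (IMU) recorded during
    two standard clinical tests of dynamic balance ability: the Timed Up and
    Go test (TUG) and the six-minute walk test (6MWT). The package provides a
    synthetic cohort generator with ground truth, zero-phase Butterworth
    preprocessing, angular-velocity threshold segmentation of the six TUG
    sub-tasks, a 132-feature engineering scheme (111 TUG descriptive and
    timing features, 21 6MWT gait-quality features including step and stride
    regularity, symmetry index, harmonic ratio and approximate entropy), and
    a gradient-boosted regression of age with Bayesian hyperparameter tuning,
    MAE/MAPE evaluation and normalized feature-importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
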