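Package: pupilkit
Title: Preprocessing and Statistical Analysis of Task-Evoked Pupillometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tidyverse-native workflow for trial-based cognitive
    pupillometry. Parses eye-tracker ASCII logs into a trial-epoched table
    in which scalar variables coexist with time-series (matrix) columns,
    reconstructs blinks by velocity-based detection with cubic-spline or
    linear interpolation, downsamples, converts arbitrary units to
    millimetres via an empirical calibration curve, applies subtractive or
    divisive baseline correction, excludes trials with outlying baseline
    pupil size, computes data-quality metrics, and tests condition effects
    on pupil time series with three procedures: a predetermined-window
    linear mixed-effects test, a cluster-based permutation test, and a
    four-fold interleaved cross-validation test. A synthetic-data generator
    with known ground truth makes the whole pipeline verifiable without an
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
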