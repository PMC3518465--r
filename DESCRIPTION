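Package: sacchoice
Title: Saccadic Choice Task Analysis with a Two-Process Race Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing saccadic choice experiments in which two
    scenes are flashed left and right of fixation and the observer saccades
    to the target category. Implements the minimal saccadic reaction time
    estimator (first 10-ms bin where correct responses significantly
    outnumber errors by a per-bin chi-square test, sustained over four
    further bins), percentile-bootstrap confidence intervals, Monte-Carlo
    permutation tests, and the object/context congruency-onset analysis on
    hits-minus-false-alarm distributions. Ships a two-process race-model
    generator of synthetic trial data with plantable accuracies, medians and
    onsets, a synthetic scene-image generator with controllable category
    statistics, and four feedforward feature models (GIST, Weibull contrast
    statistics, saliency, HMAX C1) evaluated under a repeated linear-SVM
    cross-validation protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    readr,
    rlang,
    withr,
    yaml,
    ggplot2,
    e1071,
    fitdistrplus,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
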