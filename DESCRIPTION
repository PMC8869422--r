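Package: eatseg
Title: Top-Down Detection of Eating Episodes from Wrist Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects eating episodes in day-long 6-axis wrist-motion
    recordings (15 Hz accelerometer + gyroscope). A small one-dimensional
    convolutional network classifies large sliding windows (0.5-15 minutes)
    as eating or non-eating, a hysteresis detector converts the resulting
    probability trace into episodes, and episode-, boundary- and datum-level
    metrics score detections against self-reported meals. Includes readers
    and writers for the flat-binary sensor format, subject-wise k-fold
    cross-validation with hyperparameter sweeps, and a synthetic wrist-motion
    simulator so the full pipeline can be trained and evaluated without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
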