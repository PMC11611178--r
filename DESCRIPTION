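Package: lumentrack
Title: Automated Carotid Artery Diameter Tracking from A-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for tracking the carotid artery
    diameter from single-scanline (A-mode) ultrasound streams. Includes a
    synthetic carotid phantom generator with exact ground truth, Hilbert
    envelope preprocessing, response-vector label construction, a compact
    convolutional region-of-interest detector that locates the lumen center,
    a convolutional regression network that estimates the arterial diameter
    per frame, Savitzky-Golay post-smoothing, the full evaluation metric
    suite, and a leave-one-subject-out cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
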