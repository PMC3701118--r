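Package: tactlearn
Title: Simulation and Analysis of Feedback-Biased Vibrotactile Perceptual
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation of a vibrotactile frequency
    discrimination paradigm in which biased "same"/"different" feedback
    reshapes perceptual acuity around a 16 Hz reference. Provides pulse-train
    stimulus construction, signal-detection observers with an adaptable
    readout-noise component and decision criterion, interleaved 3-down-1-up
    acuity staircases with reversal-based JND estimation, a Gaussian biased
    feedback engine with finite draw pools and an expectation-balanced reward
    schedule, full five-phase session orchestration for single subjects and
    cohorts, and an analysis stage that fits Gaussian response distributions,
    computes normalized JND changes, and runs the nonparametric group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
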