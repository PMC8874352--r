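Package: blinkhazard
Title: Blink Timing as a Readout of Temporal Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying oculomotor inhibition and
    temporal predictions from eye-blink timing during isochronous auditory
    stimulation. Generates five-tone target-detection protocols and their
    hazard-rate model of target probability, simulates cohorts of continuous
    EOG/frontal-channel recordings with ground-truth blink and saccade
    events, detects and quality-tiers blinks with a landmark-fitting
    stereotype detector, quantifies entrainment of the blink point process
    to the stimulus rate by FFT, describes blink-latency histograms with
    five-Gaussian fits and chi-square bootstrap distances, estimates
    position-wise pre-stimulus suppression with robust slopes and one-sample
    sign-flip cluster permutation tests, and scores saccades with a
    two-class Gaussian-mixture feature model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
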