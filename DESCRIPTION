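Package: wristppg
Title: Heart Rate Variability and Pulse Wave Morphology from Wrist-Worn
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing low-sample-rate (32 Hz)
    wrist-worn photoplethysmography (PPG) recorded overnight. Provides a
    synthetic two-cohort PPG generator with known ground-truth physiology;
    preprocessing (zero-phase Butterworth band-pass filtering, motion-artifact
    detection via the Signal Instability Index); pulse segmentation with
    fiducial-point detection on the waveform and its first and second
    derivatives; a catalogue of 67 features per 5-minute segment (30 heart
    rate variability features spanning time-domain, frequency-domain,
    non-linear, phase-rectified signal averaging and heart rate fragmentation
    analyses, plus 37 pulse-wave morphology features), optionally stratified
    by sleep stage; and group-comparison statistics with stepwise-forward
    feature ranking and incremental logistic-regression classification
    evaluated by cross-validated AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
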