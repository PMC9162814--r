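Package: qrsnet
Title: Residual 1D-CNN QRS Detection and SVM Exercise-Intensity
    Classification for Wearable ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-testable pipeline for wearable single-channel ECG
    exercise monitoring: a synthetic ECG generator with known R-peak ground
    truth and the three classical noise classes (EMG, powerline, baseline
    wander); a three-filter denoising chain; a residual one-dimensional
    convolutional neural network that classifies fixed-length windows as
    R-centered or not and drives a sliding-window R-peak detector; RR-interval
    and time-domain heart-rate-variability features; and a radial-basis-kernel
    support-vector classifier of three MET-defined exercise-intensity levels.
    Includes a minimal WFDB (MIT-BIH dialect) reader/writer and
    tolerance-based detection scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
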