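Package: fmgposture
Title: Real-Time Forearm Force-Myography Posture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for classifying
    upper-extremity postures from an eight-channel force-sensing-resistor
    (FSR) forearm strap. Provides a physically motivated synthetic sensor
    model (voltage-divider FSR sensing, response delays, transitions,
    repetition jitter, noise and drift), the streaming preprocessing chain
    (causal low-pass filtering, moving-average decimation, train-time
    min-max normalization), a non-kernel sigmoid extreme learning machine
    trained in closed form by regularized least squares, the six-posture
    drinking-task training and testing protocol, and delay-compensated
    real-time evaluation with per-class accuracy, response-delay
    estimation and random-base stability analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
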