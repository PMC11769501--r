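Package: harshift
Title: Robustness of Deep Human Activity Recognition Models Under Sensor Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how subject, sensor-orientation, wearing-position
    and device variability degrade deep human activity recognition (HAR) models
    trained on wrist-worn tri-axial accelerometer data. Provides a synthetic
    multi-sensor IMU session generator with controllable variability factors,
    the standardisation / sliding-window / weighted-sampling preprocessing
    pipeline, from-scratch implementations of three hybrid CNN-recurrent
    architectures (DeepConvLSTM, TinyHAR, Attend-and-Discriminate) with exact
    parameter accounting, a deterministic Adam training loop with early
    stopping and learning-rate annealing, an iterative multiscale-kernel
    Maximum Mean Discrepancy (MMD) estimator for distribution shift, and a
    leave-one-subject-out evaluation protocol linking per-fold MMD to F1
    performance, including compounding-variability scenarios in the style of
    the REALDISP ideal/self placement study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
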