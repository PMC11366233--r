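Package: grfest
Title: Ground Reaction Force Estimation from Wearable Insole and IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses treadmill running sessions recorded by a
    pressure insole, a shoe-mounted inertial measurement unit and an
    instrumented treadmill. Provides a synthetic session generator with a
    known forward model, zero-phase Butterworth filtering, threshold-based
    ground-contact detection, stance-only pressure-log reconstruction,
    stride-time correlation alignment of independently clocked devices,
    centre-of-pressure computation, assembly of standardized per-contact
    feature matrices, a bi-directional LSTM sequence-to-sequence regressor
    trained with Adam on an RMSE objective, and leave-one-subject-out
    evaluation with Bland-Altman agreement analysis and permutation feature
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    splines,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
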