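Package: srwalker
Title: Gait Symmetry, Neuromuscular and Stability Analytics for Sensor-Instrumented Rehabilitation Walkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal sensor data recorded by an
    instrumented rehabilitation walker: bilateral handlebar force streams,
    surface electromyography (sEMG) and tri-axial walker acceleration.
    Implements the Robinson Force Symmetry Index with per-day trajectories
    and cohort summaries, a closed-loop vibrotactile feedback simulator,
    tilt-based walker instability detection, an sEMG conditioning chain
    (zero-phase Butterworth band-pass and wavelet denoising) with paired
    longitudinal statistics, from-scratch Gaussian Process Regression with
    marginal-likelihood hyperparameter optimisation for rehabilitation
    trajectory modelling, and stride-time variability analysis with group
    comparison.  A seeded synthetic multimodal generator reproduces the
    statistical structure of a 15-day rehabilitation cohort so every stage
    is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
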