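Package: tensiometry
Title: Shear Wave Tensiometry Wave-Speed Estimation with Kalman Sensor Fusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating tendon shear-wave speed from skin-mounted
    accelerometer arrays excited by an impulsive tapper. Provides a tensiometer
    data simulator (underdamped second-order tap responses, band-limited sensor
    noise, gait-cycle wave-speed profiles), normalized cross-correlation
    time-delay estimators with sub-sample cosine interpolation, an empirical
    calibration relating correlation strength to delay-estimate variance, and a
    Kalman filter that fuses inter-sensor travel times with tap-to-tap arrival
    changes to produce optimized wave-speed trajectories, together with
    simulation experiments quantifying the accuracy gains from filtering and
    redundant sensors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
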