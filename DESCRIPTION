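Package: wrikit
Title: Wrist Rotation Imitation Analysis from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating wrist rotation imitation (WRI) ability from
    dual-wrist six-axis inertial recordings. Provides a session data model and
    file readers for a three-block imitation protocol, a synthetic session
    simulator with group-structured kinematics, accelerometer least-squares and
    gyroscope Allan-deviation calibration, a conditioning chain (shape-preserving
    cubic interpolation, zero-phase Butterworth low-pass, scalar Kalman
    smoothing), extraction of three kinematic metrics (total rotation time,
    rotation amplitude, left/right symmetry), Gesell/CARS/PEP-3 clinical-scale
    scoring, aligned-rank-transform factorial ANOVA with ART-C post-hoc
    contrasts, Spearman correlation screens, and a five-algorithm classification
    benchmark with ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal,
    pracma,
    car,
    MASS,
    class,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
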