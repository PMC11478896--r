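Package: wheelkin
Title: Handrim Kinetics Estimation from Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates handrim reaction forces (Fx, Fy) and the sagittal
    propulsion moment (Mz) during manual wheelchair propulsion from a single
    wrist-worn inertial measurement unit per hand. Provides push-cycle
    segmentation and RMS normalization of quasi-periodic propulsion signals,
    a multi-input single-output Hammerstein-Wiener block-oriented nonlinear
    model identified by prediction-error minimization with an exhaustive
    pole/zero order search, a bidirectional LSTM sequence-regression
    baseline, a synthetic propulsion-recording generator for fully
    reproducible experiments, and an agreement/error evaluation suite
    (RMSE/MAE tables, Bland-Altman limits of agreement, peak-level ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
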