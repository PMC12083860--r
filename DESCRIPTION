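Package: patchkin
Title: Ion-Channel Kinetics Analysis of Whole-Cell Voltage-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage analysis toolkit for whole-cell voltage-clamp
    recordings. Stage one screens recordings with a weighted k-nearest-
    neighbour anomaly detector; stage two classifies the surviving
    recordings into six ion-channel kinetic categories with a three-branch
    1D-convolutional BiLSTM attention network operating on phase-segmented,
    z-scored current traces. A conductance-based (Hodgkin-Huxley style)
    simulator generates labelled synthetic recordings for all six normal
    categories and four anomaly types, so every stage is testable without
    laboratory data. Downstream kinetics analyses cover peak currents,
    current density, current-voltage curves, activation thresholds,
    reversal potentials and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    randomForest,
    ranger,
    rpart,
    xgboost,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
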