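Package: shoulderkin
Title: Marker-Less Shoulder Kinematics Validation and Personalized Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates shoulder-abduction exercises observed simultaneously by a
    marker-based optical motion-capture reference and a marker-less depth-camera
    skeleton tracker, computes three 3D joint angles (shoulder abduction alpha,
    elbow extension beta, and the arm-body transverse angle gamma) with a
    virtual-shoulder construction and last-observation-carried-forward gap
    filling, quantifies between-system agreement (MAE, RMSE, R-squared, Spearman,
    Bland-Altman difference plots, Friedman and Wilcoxon tests), and applies
    personalized per-subject regression calibration across ten regressor
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    yaml,
    jsonlite,
    glmnet,
    e1071,
    rpart,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
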