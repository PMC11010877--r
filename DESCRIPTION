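Package: caninefc
Title: Longitudinal Resting-State Functional Connectivity Analysis for Working Dogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for edge-wise resting-state functional connectivity (FC)
    analysis of longitudinal working-dog cohorts scanned at three timepoints
    across detection training. Covers temporal preprocessing of ROI time
    series (framewise displacement, motion censoring with interpolation,
    detrending, nuisance regression, ideal band-pass filtering), Pearson FC
    matrices with Fisher-z handling, selection of a flexible "periphery"
    network whose training-related FC changes track changes in an integrated
    behavioral score, selection of a stable "core" network whose pre-training
    FC predicts eventual training success via a cross-validated
    ridge-penalised logistic classifier with pooled ROC/AUC, and cross-cohort
    connectivity-fingerprint matching. A synthetic cohort generator with
    planted core/periphery structure makes every stage testable end to end
    without access to restricted scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    signal,
    optparse
Config/testthat/edition: 3
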