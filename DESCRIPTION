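Package: gazemarker
Title: Eye-Movement Biomarkers for Simulated Glaucomatous Visual Field Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of whether natural eye movements discriminate
    simulated glaucomatous visual-field loss while free-viewing videos and images.
    Provides a seeded synthetic gaze-data generator with planted group effects,
    24-2 perimetry handling (integrated visual field, mean-deviation severity
    classes, gaze-relative scotoma masks), velocity/acceleration saccade-fixation
    event detection, four eye-movement biomarkers (median saccade amplitude, 95%
    bivariate contour ellipse area, proportion of saccades landing on visual-field
    loss locations, per-frame kernel-density gaze-similarity score), nonparametric
    group statistics with rank effect sizes, ROC diagnostic accuracy including
    sensitivity at fixed specificity and windowed temporal AUC, and a multi-feature
    kernel-PCA plus AdaBoost classifier evaluated by leave-one-out.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
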