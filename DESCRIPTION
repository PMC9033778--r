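Package: antagnet
Title: Antagonistic Functional Connectivity and Connectome-Based
    Prediction of Motor Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes resting-state functional connectivity into
    accordance and discordance profiles via extreme-event binarization of
    z-scored ROI time series, and builds connectome-based predictive
    models (CPM) of a clinical motor score with single-component partial
    least squares regression, leave-one-out cross-validation, permutation
    and dependent-correlation (Steiger's z) inference, network-level
    weight aggregation, and disease-stage residual analysis. Includes a
    synthetic multi-subject cohort generator with planted
    behavior-coupled antagonistic edges so the full pipeline can be
    exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
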