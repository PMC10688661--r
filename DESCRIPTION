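Package: slidemark
Title: Sliding-Landmark Dynamic Prediction for Recurrent-Event Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic prediction of event-free probabilities in
    recurrent-event trials by landmarking: sliding landmark datasets
    (truncation at a landmark time, administrative censoring at a
    horizon), per-landmark Cox fits, the stacked super prediction
    dataset, stratified and unstratified landmark supermodels with
    polynomial basis functions of the landmark time, landmark-specific
    Breslow baseline hazards and conditional event-free probabilities.
    Includes the supporting model suite for recurrent events (Andersen-
    Gill and gap-time Cox models, first-event Cox, shared gamma-frailty
    models fitted by an EM profile-likelihood algorithm, Kaplan-Meier
    curves by event order), counting-process CSV input/output, and a
    calibrated synthetic two-arm recurrent-event cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
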