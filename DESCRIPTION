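Package: earstress
Title: Stress Assessment from Wearable Ear-EEG and Head ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for two-channel behind-the-ear EEG and
    single-channel head ECG recorded during laboratory stress protocols
    (Stroop and mental-arithmetic stressors alternating with rest). Detects
    R-peaks with a Pan-Tompkins detector tuned for low-amplitude head ECG,
    derives time- and frequency-domain heart rate variability features,
    computes EEG band powers and hemispheric asymmetries after amplitude-based
    EOG artifact rejection, and classifies stress versus rest with a linear
    support vector machine under stratified five-fold cross-validation.
    Includes synthetic signal and feature-cohort generators with exact ground
    truth so every stage can be validated without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
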