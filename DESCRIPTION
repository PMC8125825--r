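Package: manuclass
Title: Classification of Manual Activities from Wearable Gyroscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies repetitions of manual activities of daily living into
    five categories (unimanual; bimanual with a stabilizing hand, with or
    without finger activity; bimanual with both hands active, with or without
    finger activity) from six wrist- and finger-worn triaxial gyroscopes.
    Computes per-sensor angular-speed norms, hand and finger aggregate
    signals, the hands ratio (HR) and fingers-to-wrist ratio (FWR), learns
    ROC-optimal (Youden) cutoffs, applies a three-step threshold decision
    tree, and validates with leave-one-subject-out cross-validation. Includes
    a synthetic six-sensor dataset generator with ground-truth annotations so
    the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
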