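Package: flowsense
Title: Predicting Cognitive Flow States from Wrist-Worn Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for detecting self-reported
    cognitive flow from multichannel wearable sensor data. Reads Empatica
    E4-style session exports (heart rate, skin temperature, electrodermal
    activity, 3-axis acceleration), removes device-calibration artifacts,
    computes 30 baseline-relative distributional features per task, measures
    flow from the 9-item Flow State Scale with a Rasch Rating Scale Model
    (joint maximum likelihood, infit/outfit diagnostics, residual principal
    components, separation reliability, Wright map), selects features with a
    two-level forward-stepwise logistic regression using likelihood-ratio
    entry, and evaluates logistic and Gaussian naive Bayes classifiers under
    between-participant, stratified 10-fold, resubstitution and leave-one-out
    cross-validation with permutation feature importance. A seeded
    synthetic-study generator with known ground truth makes every stage
    testable without access to human-subjects data.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
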