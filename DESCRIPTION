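Package: glucopair
Title: Paired-Round Deep Learning for Noninvasive Blood Glucose Estimation
    from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating fasting blood glucose from finger
    photoplethysmography (PPG) recordings using a paired-round
    ("differential cell") convolutional neural network. The package covers
    the full pipeline: a synthetic PPG/glucose simulator with a tunable
    morphology-glucose coupling, Butterworth band splitting and
    bigger-fall-side-slope pulse annotation, morphological feature
    extraction, adjacent-round sample pairing, a small pure-R 1-D CNN
    regressor trained with Adam, a two-stage prediction-confidence
    screening algorithm with ROC-based threshold selection, and Clarke
    Error Grid evaluation with the usual accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
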