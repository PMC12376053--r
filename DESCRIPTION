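Package: pod12risk
Title: Risk Scoring and Chaotic Time-Series Forecasting of Early
    Progression in Diffuse Large B-Cell Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying progression of disease within 12 months
    (POD12) in diffuse large B-cell lymphoma. Implements a points-based
    clinical risk score built from six dichotomized factors (LDH,
    beta2-microglobulin, Ann Arbor stage, ECOG performance status, NLR and
    SII) with full 2x2 diagnostic validation, Youden-index cut-off
    selection, adjusted logistic regression reporting and a single
    proportion power check; and a chaos-theory forecasting branch:
    phase-space reconstruction (mutual-information delay, false nearest
    neighbours), a self-contained CNN-LSTM one-step predictor trained by
    backpropagation with Adam, a comprehensive risk index with a four-level
    classification, and a general regression neural network whose smoothing
    factor is selected by particle swarm optimization. Includes synthetic
    cohort and monitoring-series generators so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
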