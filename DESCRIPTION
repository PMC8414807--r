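Package: ffrscore
Title: Multi-Factor Risk Weighting and Scoring for Fractional Flow Reserve
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weights independent clinical risk factors for hemodynamically
    significant coronary stenosis (fractional flow reserve, FFR <= 0.8) with an
    analytic hierarchy process: pairwise importance-degree matrices on the
    Saaty 1-9 scale (built directly or from published odds ratios),
    principal-eigenvector weights, consistency index and random consistency
    ratio diagnostics, and propagation of local weights through a three-layer
    hierarchy. Converts the top-ranked factors into a 10-point bedside scoring
    form, scores patient cohorts, and evaluates discrimination with ROC/AUC,
    Youden-index cutoff selection and confusion-matrix metrics with confidence
    intervals. Includes a seeded synthetic cohort generator calibrated to
    published marginal distributions and a latent logistic FFR label model for
    download-free end-to-end testing, plus CSV/YAML/JSON readers and writers
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
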