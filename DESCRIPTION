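Package: nutricr
Title: Derivation, Validation and Application of the NUTRIC Nutrition Risk Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nutrition risk in the intensive care unit with the
    NUTRIC (NUTrition Risk In the Critically ill) score. Provides the fixed published
    scoring table (with an IL-6-optional variant), the full derivation pipeline that
    turns categorized predictors into an integer-points score via single-predictor
    logistic regression (quintile categorization, points from rounded log odds ratios,
    category collapsing, boundary rounding, and exclusion rules), model validation
    (c-index, Cox-Snell and Nagelkerke R-squared, Hosmer-Lemeshow calibration,
    variance inflation factors, split-half cross-validation, comparison models),
    outcome analyses (ventilator-free-day correlations, mechanical-ventilation
    duration with a pure-error lack-of-fit test, nutritional adequacy, and the
    score-by-adequacy effect-modification likelihood-ratio test), and a seeded
    synthetic ICU-cohort generator emulating the statistical structure the analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car
Config/testthat/edition: 3
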