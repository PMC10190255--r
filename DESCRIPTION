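Package: crrtmipd
Title: Evaluation of Population Pharmacokinetic Models for Precision Dosing
    of Meropenem Under Continuous Renal Replacement Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to encode population pharmacokinetic (PopPK) models of
    meropenem declaratively, predict plasma concentrations a priori (from
    patient covariates alone) or by single-sample maximum a posteriori (MAP)
    Bayesian forecasting, and score candidate models with symmetric
    prediction-error statistics (MPE/MAPE with bootstrap confidence
    intervals), normalized prediction distribution errors (NPDE), and
    prediction-corrected visual predictive checks (pcVPC). Ships eight
    published candidate models for critically ill patients on continuous
    renal replacement therapy (CRRT) and a synthetic-cohort generator that
    emulates the covariate, dosing, and sampling structure of a two-center
    CRRT cohort, so the full model-evaluation workflow can be exercised
    end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
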