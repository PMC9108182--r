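Package: eposgait
Title: External Validation Pipeline for the EPOS Independent-Gait Prediction Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating the Early Prediction of functional
    Outcome after Stroke (EPOS) logistic prediction model for independent gait,
    and for validating other fixed-coefficient binary risk scores with the same
    workflow. Provides cohort ingestion with strict range checking and
    eligibility filtering, the published day-2 and day-9 EPOS equations,
    multiple imputation of missing predictors by chained equations (predictive
    mean matching and logistic draws), discrimination (ROC/AUC with DeLong
    confidence intervals), classification (sensitivity, specificity, predictive
    values, no-information-rate test), calibration (grouped observed vs
    predicted probabilities with Wilson intervals), pooling across imputations
    by Rubin's rules, and a seeded synthetic-cohort generator that emulates the
    case-mix of the validation cohorts so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
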