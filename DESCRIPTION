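Package: coxstack
Title: Hybrid Boosted and Penalized Cox Models for Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for deriving and validating hybrid statistical and
    machine-learning survival risk models on electronic-health-record style
    cohorts. A gradient-boosted tree ensemble is trained with the Cox
    partial-likelihood objective and its risk score is stacked as a covariate
    into a ridge-penalized Cox proportional hazards model over a small set of
    mandatory clinical predictors, with a Breslow baseline for absolute
    10-year risk. Includes cohort assembly from longitudinal records,
    synthetic cohort simulation with known ground truth, eligibility
    screening, chained-equation imputation with predictive mean matching,
    LASSO variable shortlisting, and a validation suite (Harrell's C,
    decile calibration against Kaplan-Meier, calibration slope,
    calibration-in-the-large, IPCW Brier score, decision-curve analysis,
    bootstrap and repeated cross-validation, recalibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    xgboost,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
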