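Package: glycotwin
Title: Digital-Twin Simulation and Prediction of Postprandial Glycemic Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale digital-twin pipeline for postprandial glycemic
    response (PPGR) in type 2 diabetes. Simulates cohorts of virtual patients
    with continuous glucose monitoring (CGM), meal, activity and sleep streams
    from an explicit ground-truth meal-response mechanism; cleans and imputes
    the streams (robust outlier flagging, gap interpolation, multiple
    imputation by chained equations with Rubin pooling); engineers the
    37-feature predictor rows (glucoseMax extraction, medication-penalized
    baselines, meal and temporal-context features); trains and validates a
    gradient-boosted PPGR predictor under temporal-gap k-fold cross-validation;
    and drives a multi-objective dietary recommendation engine with
    Green/Orange/Red-For-You food classification and feedback-driven threshold
    adjustment. Includes time-in-range and glycemic-variability metrics and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    nnet,
    randomForest,
    ranger,
    rlang,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
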