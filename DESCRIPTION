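Package: glycoregress
Title: Glycemic-Aware Evaluation and Oversampling for Blood Glucose Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for 30-minute-ahead blood glucose forecasting from
    continuous glucose monitor (CGM) traces, with an emphasis on the
    imbalance between glycemic ranges. Provides gap-aware sliding-window
    featurization of CGM time series, pseudolabel-based oversampling for
    regression (random duplication, SMOTE and ADASYN variants that
    synthesize the numeric target together with the features),
    range-partitioned mean absolute relative difference (MARD) metrics and
    Clarke error grid analysis, a registry of baseline regressors with a
    uniform train/predict contract, a benchmark harness over the
    model-by-oversampler-by-patient grid with Friedman, Nemenyi and paired
    t statistics, and a seeded synthetic CGM generator for testing the
    pipeline without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    FNN,
    glmnet,
    Rcpp,
    readr,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
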