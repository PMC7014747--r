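Package: debulkr
Title: Preoperative Prediction of Primary Optimal Cytoreduction in
    Advanced Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating noninvasive preoperative
    models that predict suboptimal primary cytoreduction in advanced
    epithelial ovarian cancer from serum HE4 and CA125 together with
    clinicopathological covariates. Provides ROC-based marker cutoff
    selection (Youden index), per-parameter diagnostic-efficacy tables,
    a points-based Predictive Index Value (PIV) score with threshold
    sweeps, multivariable logistic regression fitted by iteratively
    reweighted least squares with split-sample validation and
    Hosmer-Lemeshow calibration, Hanley-McNeil AUC standard errors and
    power, and a seeded synthetic-cohort generator calibrated to
    published cohort characteristics so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
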