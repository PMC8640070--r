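Package: stratifs
Title: Confound-Aware Information-Theoretic Feature Selection and Risk
    Prediction for Case-Control Dosage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter feature selection on imputed allele-dosage tables using
    seven mutual-information criteria (MIM, MIFS, JMI, mRMR, CMIM, ICAP,
    DISR) with histogram (plug-in) estimators, stratification-based
    mitigation of confounders such as age at disease onset and principal
    components, bootstrap vote/rank stability aggregation across criteria,
    and nested cross-validated benchmarking of risk-prediction classifiers
    with decision-curve analysis. Includes a synthetic case-control cohort
    generator that reproduces ascertainment-induced confounding so every
    stage is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
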