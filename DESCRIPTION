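Package: ercpredict
Title: Validation Toolkit for an Early-Reconnection Prediction Model in
    Cryoballoon Pulmonary Vein Isolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating a vein-level risk score that predicts
    early reconnection or dormant conduction (ERC) after cryoballoon
    pulmonary vein isolation. Provides readers for vein-level and
    freeze-trace tables, biophysical feature extraction from
    temperature-time curves (freeze area under the curve, freeze
    magnitude, warming times), the linear ERC risk score with cutoff
    classification and a bedside decision table, a full
    diagnostic-accuracy suite (sensitivity, specificity, likelihood
    ratios, prevalence-adjusted predictive values, ROC curves with
    DeLong confidence intervals, expected-count projections,
    cross-cohort cutoff comparison), Kaplan-Meier survival with
    blanking-period and antiarrhythmic-drug censoring rules, and a
    synthetic cohort generator so every stage can be exercised without
    patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr
Suggests:
    broom,
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
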