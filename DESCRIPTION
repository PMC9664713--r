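Package: adheval
Title: Adherence Measurement Evaluation for Predicting Viral Load Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score antiretroviral-therapy adherence from self-report,
    pharmacy refill counts and real-time medication monitoring (RTMM) device
    openings; to dichotomize adherence on a cut-off grid and build any-measure
    composite classifications; to evaluate each measure's ability to predict a
    detectable HIV viral load via sensitivity, specificity, predictive values,
    empirical ROC curves, AUC and the closest-to-top-left optimal cut-off; and
    to fit covariate-adjusted logistic regressions of virological failure on
    dichotomized adherence. A synthetic cohort generator with explicit
    measurement-error mechanisms (self-report over-reporting, unknown leftover
    pills, pocket dosing, device outages) emulates the data structure of an
    adherence-monitoring trial so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
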