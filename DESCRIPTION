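Package: tlfbtrials
Title: Timeline Follow-Back Drinking Endpoints and Predictor Analysis for
    Alcohol Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the FDA-guided binary drinking outcomes used in alcohol
    use disorder (AUD) pharmacotherapy trials -- total abstinence, no heavy
    drinking days, a two-or-more WHO risk drinking level reduction, and
    research completion -- from daily timeline follow-back (TLFB) calendars,
    with worst-case imputation of unreported days.  Harmonizes participant
    baseline tables across multi-site trials, screens predictors with
    logistic regression under Bonferroni correction, locates operational
    cutoffs for continuous predictors with ROC curves and Youden's index,
    and tabulates outcomes against cutoffs and baseline risk strata.  A
    configurable synthetic multi-study trial generator with known truth
    supports parameter-recovery testing when the source clinical datasets
    are access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
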