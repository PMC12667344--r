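Package: peratio
Title: Cross-Validated, Bootstrap-Calibrated Cutoff Evaluation for the
    sFlt-1/PlGF Preeclampsia Biomarker Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating diagnostic thresholds of the serum
    sFlt-1/PlGF ratio for short-term (14-day) prediction of preeclampsia.
    Implements cohort ingestion with eligibility filtering and baseline
    tables, a full confusion-matrix metric suite with ROC/AUC and
    Youden-index optimal cutoff selection, logistic-regression scoring under
    stratified k-fold cross-validation nested inside bootstrap resampling
    with percentile confidence intervals (including a CI on the optimal
    cutoff itself), fixed-cutoff evaluation, group and cutoff comparisons
    (Z-tests, Mann-Whitney U, chi-square), and a synthetic cohort generator
    with stratified lognormal ratio distributions calibrated to published
    median/IQR summaries, including analytic ground truths for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
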