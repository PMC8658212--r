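Package: tnref
Title: Age- and Sex-Stratified Upper Reference Limits for High-Sensitivity
    Cardiac Troponin T
Version: 0.1.0
Authors@R:
    person("Chris", "Weber", email = "chris.weber@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving nonparametric upper reference limits (99th
    percentiles) of high-sensitivity cardiac troponin T stratified by age,
    sex, and renal function.  Implements the detection-limit floor transform
    for left-censored assay values, exact order-statistic confidence
    intervals for quantiles, CKD-EPI estimated glomerular filtration rate,
    a cardiac-healthy cohort exclusion cascade with audit trail, stratified
    reference tables with a minimum-group-size rule, sliding-window
    ("floating") percentile curves and surfaces, Spearman rank correlation,
    and a calibrated synthetic cohort generator with known ground-truth
    stratum quantiles for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
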