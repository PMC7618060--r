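Package: lowprev
Title: Feasibility Calculations for Clinical Risk Prediction with
    Low-Prevalence Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calculators and Monte-Carlo simulators for planning clinical
    risk-prediction studies when the outcome is rare. Implements the
    closed-form algebra linking prevalence, sensitivity, specificity,
    positive predictive value, relative risk and likelihood ratios for a
    dichotomized risk marker; two-proportion sample-size and power
    calculations with unequal allocation for detecting a binary risk
    factor; the events-per-variable feasibility rule; curve tables showing
    required sample size against effect size and required relative risk
    against sensitivity; and a seedable cohort simulator that validates
    every closed form empirically. A command-line interface produces a
    combined feasibility report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
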