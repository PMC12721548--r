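Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling of First-Line
    Immunochemotherapy for Extensive-Stage Small-Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead)
    partitioned-survival cohort model for the cost-utility evaluation of
    socazolimab plus carboplatin/etoposide against chemotherapy alone in
    extensive-stage small-cell lung cancer, from the Chinese healthcare
    system perspective.  Provides closed-form parametric survival families
    with censored maximum-likelihood fitting and AIC/BIC model selection,
    Kaplan-Meier pseudo individual-patient-data reconstruction from
    digitized survival curves, per-cycle cost and quality-adjusted
    life-year accrual with discounting, incremental cost-effectiveness
    ratios, price-threshold analysis, and deterministic (tornado) and
    probabilistic (CEAC, cost-effectiveness plane) sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
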