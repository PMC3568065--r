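Package: gefcea
Title: Cost-Effectiveness Model of Gene-Guided Gefitinib Maintenance
    Therapy in Advanced NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A four-state semi-Markov cohort model of gene-guided gefitinib
    switch-maintenance therapy for advanced EGFR mutation-positive
    non-small cell lung cancer, evaluated from the Chinese health-care
    payer perspective.  Implements Weibull survival extrapolation of
    Kaplan-Meier data with proportional-hazards adjustment, discounted
    cost and QALY accrual with patient-assistance-program (GPAP) drug
    pricing, incremental cost-effectiveness ratios and net monetary
    health benefit, one-way (tornado), two-way and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves,
    and a synthetic pseudo-individual-patient-data generator for testing
    the curve-fitting stage by parameter recovery.
License: MIT
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
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
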