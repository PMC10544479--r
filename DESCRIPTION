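Package: abxcea
Title: Cost-Effectiveness Analysis of Antibiotic Prescribing Strategies for
    Paediatric Respiratory Tract Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based decision-analytic cost-effectiveness modelling of
    delayed, immediate and no antibiotic prescription for uncomplicated
    respiratory tract infections in children seen in primary care. Implements
    a 30-day decision-tree model with societal costing (healthcare direct,
    non-healthcare direct, indirect and antimicrobial-resistance costs),
    quality-adjusted life-day (QALD) effectiveness, incremental
    cost-effectiveness ratios with strict and extended dominance, net monetary
    benefit, one-way tornado sensitivity analysis, probabilistic sensitivity
    analysis with beta/gamma/Dirichlet parameter distributions,
    cost-effectiveness planes and acceptability curves, and a synthetic
    individual-patient-data generator with parameter-recovery estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
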