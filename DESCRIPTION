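Package: crushkit
Title: Analysis Pipeline for Large-Animal Crush-Syndrome Kidney Injury Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of crush-syndrome (rhabdomyolysis)
    acute kidney injury studies with protocolized critical care: measured-GFR
    estimation from iohexol plasma concentration-time data by compartmental
    fitting and dose/AUC, classification of renal recovery and a priori
    exclusions, detection and time-to-event analysis of protocolized
    hyperkalemia interventions (Kaplan-Meier, log-rank), exact and asymptotic
    2x2 inference, Welch tests from summary statistics, Sidak multiplicity
    adjustment, and Monte Carlo power estimation for a two-arm binary-outcome
    clinical trial. A seeded synthetic-cohort generator reproduces the
    statistical structure the analysis assumes, so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
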