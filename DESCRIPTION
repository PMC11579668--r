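Package: lleesim
Title: Local-Level Economic Evaluation of Hypoglycemia-Prevention
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for local-level economic evaluation (LLEE)
    of hospital service interventions that prevent hospital-acquired
    hypoglycemia.  Generates admission-level cohorts of categorized blood
    glucose excursions calibrated to printed baseline summaries, applies
    published or expert-elicited intervention effects event-by-event via a
    stochastic prevention rule with bootstrap resampling, calibrates
    relative risks reported on heterogeneous outcome measures (events,
    patient-days, patients) onto a common event-level measure, converts
    odds ratios and 2x2 tables into relative risks, and assembles
    cost-consequence tables covering hospital-acquired-complication
    funding penalties, occupied bed-days, nursing time, and staff costs
    under three-point elicited scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
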