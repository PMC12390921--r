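Package: fortcost
Title: Activity-Based Cost Modelling for Salt Fortification Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the total and incremental 10-year cost of large-scale
    salt fortification programs (iodized, dual, triple and quadruple fortified
    salt) with activity-based cost models: premix costing for sprayed and
    extruded fortificants, equivalent-annual-cost annualization of capital,
    fortified-salt demand from population and per-capita consumption,
    per-year and annual-average cost reports with stakeholder, per-capita and
    per-metric-ton breakdowns, and deterministic one-way and combined
    sensitivity analysis. Ships a calibrated parameter set for Ethiopia's
    salt iodization program and its hypothetical multiple-micronutrient
    expansions, plus a generator of randomized parameter books for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
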