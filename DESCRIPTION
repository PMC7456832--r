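Package: cdemed
Title: Controlled-Direct-Effect Mediation Estimators Under Mediator-Outcome Confounding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of total, controlled direct, and indirect effects in
    single-mediator models with measured baseline or post-treatment
    confounders and an unmeasured mediator-outcome confounder. Implements
    regression with adjustment, inverse propensity weighting for a continuous
    (or binary) mediator with optional weight truncation, sequential
    g-estimation, and doubly robust sequential g-estimation, together with
    percentile bootstrap confidence intervals and a Monte Carlo simulation
    framework that evaluates bias, mean squared error, relative bias, and
    interval coverage over factorial condition grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
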