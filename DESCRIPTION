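Package: pgxcea
Title: Cost-Effectiveness Modelling of Pharmacogenetic-Guided Antidepressant Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage health-economic evaluation of CYP2D6/CYP2C19 panel-guided
    antidepressant prescribing against standard of care in major depressive
    disorder: a six-week decision tree over metabolizer-class cells, a lifetime
    Markov cohort model with three-month cycles and age-trended mortality, and
    the full uncertainty apparatus (univariate sweeps, probabilistic sensitivity
    analysis with beta/gamma/triangular sampling, cost-effectiveness
    acceptability curves, and regression tornado ranking). Ships a
    machine-readable parameterization of the published model inputs, a
    synthetic-data generator for valid random parameter sets and mortality
    schedules, and scenario/report runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
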