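Package: rrmscea
Title: Cost-Utility and Budget-Impact Modelling of Rituximab for
    Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seven-state monthly-cycle Markov cohort model comparing best
    supportive care, originator rituximab and a rituximab biosimilar in
    relapsing-remitting multiple sclerosis from a Thai health-system
    perspective. Implements deterministic cost-utility analysis (discounted
    costs, life-years, QALYs, ICERs with dominance handling), one-way and
    probabilistic sensitivity analysis with Beta/Gamma method-of-moments
    parameter distributions, cost-effectiveness acceptability curves, a
    five-year government budget-impact projection, and an individual-level
    microsimulation oracle used to validate the cohort engine and recover
    transition parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
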