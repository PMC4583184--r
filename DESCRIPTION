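Package: earcea
Title: Cost-Utility Modelling of Ear-Disease Screening Programs for
    Indigenous Children
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifetime Markov cohort model for the cost-utility analysis of
    ear-disease screening and surveillance strategies in Indigenous
    Australian children. Provides annual-equivalent costing of capital
    items and service bundles, an age- and strategy-dependent five-state
    cohort engine with discounting and half-cycle correction, incremental
    cost-effectiveness and dominance analysis, one-way deterministic
    sensitivity analysis, probabilistic sensitivity analysis with
    beta/gamma/triangular parameter distributions, cost-effectiveness
    acceptability curves, and a synthetic model generator with closed-form
    oracles for testing.
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
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
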