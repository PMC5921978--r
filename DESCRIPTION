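Package: traineesim
Title: Counterfactual Simulation of GP Specialty-Training Selection with
    Multiple Imputation
Version: 1.0.0
Authors@R:
    person("Workforce", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how alternative selection processes for UK
    general-practice specialty training would change the number of trainees
    reaching GP Registration. Provides a synthetic generator for linked
    application/training-outcome cohorts with selection-induced missingness,
    a fully-conditional-specification (chained equations) multiple-imputation
    engine with predictive mean matching, simulators for four selection
    policies (random, cut-score based, Stage 2 rank, Stage 3 rank) at a range
    of annual recruitment targets, and pooling/analytics for 3- and 5-year
    full-time-equivalent registration outcomes across imputations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
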