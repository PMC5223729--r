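Package: bnpcea
Title: Cost-Effectiveness Modelling of BNP-Guided Care in Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-state (Alive/Dead) Markov cohort model comparing B-type
    natriuretic peptide (BNP)-guided pharmacotherapy with clinically guided
    care in recently hospitalised heart-failure patients. Implements a
    parameter registry with method-of-moments distribution fitting,
    per-cycle mortality and hospitalisation hazard schedules with
    life-table extrapolation, half-cycle-corrected cost and QALY accrual,
    incremental net monetary benefit and cost-effectiveness acceptability
    curves, probabilistic and deterministic sensitivity analysis across
    three patient subgroups defined by age and ejection fraction, and a
    synthetic-data module (Gompertz-Makeham life tables, right-censored
    survival records) with exponential and Weibull proportional-hazards
    fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite,
    survival,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
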