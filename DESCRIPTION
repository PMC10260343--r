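Package: crmshift
Title: Shift-Model Continual Reassessment Method for Concurrent
    Mono- and Combination-Therapy Dose Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation tools for phase I oncology trials that
    concurrently locate the maximum tolerated dose (MTD) of an agent given
    alone and with a second agent over a 2-row dose grid. Implements the
    continual reassessment method (CRM) with shift-structured working models
    (one skeleton per hypothesized offset between the two rows' MTDs),
    likelihood-based model selection, a two-stage conduct rule, and a
    structural guarantee against MTD-order reversals. Includes parallel
    per-row 3+3 and Bayesian optimal interval (BOIN) comparator designs,
    indifference-interval skeleton calibration, a CRM sample-size
    calculator, constrained random dose-toxicity scenario generation, and a
    Monte Carlo engine for operating characteristics (correct selection,
    correct allocation, sample size, early stopping, reversal rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
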