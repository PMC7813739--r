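Package: mrmcea
Title: Cost-Effectiveness Analysis of MR-Mammography Screening in Dense Breasts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic model for the economic evaluation of
    contrast-enhanced MR-mammography (MRM) as a solitary imaging test in
    women at intermediate breast-cancer risk due to dense breast tissue.
    A decision tree over the four diagnostic outcomes (true/false
    positive/negative) feeds three-state Markov cohort models
    (alive without cancer, alive with cancer, dead) that accrue discounted
    costs and quality-adjusted life years over a five-year horizon.
    Includes expected-value and net-monetary-benefit base-case analysis,
    deterministic one-way sensitivity analysis with tornado ordering,
    a patient-level microsimulation that doubles as a stochastic oracle for
    the cohort engine, diagnostic-accuracy utilities, convention
    calibration against published per-branch results, and a reproducible
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
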