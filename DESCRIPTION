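Package: dmocea
Title: Markov Cohort Cost-Effectiveness Model of Intravitreal
    Corticosteroids for Diabetic Macular Oedema
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-eye, five-state Markov cohort model for the
    cost-effectiveness of dexamethasone intravitreal implants compared
    with triamcinolone injections in diabetic macular oedema, from the
    hospital perspective. Health states are bands of better-seeing-eye
    visual acuity with an absorbing blindness state; strategy-specific
    cycle lengths, early/late transition matrices, state-dependent drug,
    follow-up, adverse-event and rehabilitation cost accrual, QALY
    weighting, discounting, incremental cost-effectiveness ratios with
    dominance classification, willingness-to-pay decisions, and
    deterministic sensitivity analyses. Includes a seeded synthetic
    transition-matrix generator with structural validation and
    derivative-free calibration, configuration file handling, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
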