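Package: osteosim
Title: Patient-Level Microsimulation of Osteoporotic Fracture Prevention and
    Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time (annual-cycle) patient-level Markov
    microsimulation of hip, clinical vertebral and wrist fragility fractures
    in women aged 40 and over, together with a full cost-effectiveness and
    cost-utility pipeline for comparing sixteen prevention and screening
    strategies (status quo, universal primary prevention, and questionnaire-
    or BMD-based screening with CAROC 10-year risk categorisation).
    Includes a synthetic-cohort generator, calibration of baseline fracture
    hazards to lifetime-risk targets, discounted cost and QALY accrual from
    a public-payer perspective, incremental cost-effectiveness frontiers with
    strict and extended dominance, one-way and probabilistic sensitivity
    analysis, and cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
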