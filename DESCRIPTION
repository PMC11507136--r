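Package: teleCEA
Title: Cost-Effectiveness of Telehealth Versus In-Person Primary Care for
    People Living with ADRD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort modelling of primary care
    delivery for community-dwelling people living with Alzheimer's
    Disease-Related Disorders (ADRD). Implements a three-state (in-person,
    telehealth, dead) cohort model over a 10-year horizon with yearly
    cycles and 3 percent discounting, incremental cost-effectiveness
    ratios on a caregiver-burden effectiveness scale (modified 12-item
    Zarit Burden Interview), one-way sensitivity analysis, estimation of
    every model input (transition and mortality probabilities, emergency
    department and hospitalization rates and per-event costs from
    discharge length-of-stay and daily charges, delivery-mode costs,
    caregiver burden) from person-level records, and a synthetic cohort
    and discharge-record generator so the whole analysis runs end-to-end
    without access to the underlying claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
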