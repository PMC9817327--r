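Package: txacea
Title: Cost-Utility and Budget-Impact Modelling of Tranexamic Acid for
    Postpartum Haemorrhage Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cost-utility modelling of adding intravenous
    tranexamic acid (TXA) to standard postpartum-haemorrhage (PPH) care in
    Indian public health facilities.  Provides a two-arm decision tree over
    facility levels and PPH types with symbolic pathway probabilities, cost
    and utility payoffs with configurable QALY discounting, deterministic
    base-case analysis (ICUR, net monetary and health benefit, clinical event
    counts), one-way and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a five-year national budget
    impact model with phased uptake, a patient-level microsimulation oracle
    for validating cohort expectations, and a calibration routine for the
    under-determined structural knobs (facility-level case mix, discounting
    convention, mortality allocation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
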