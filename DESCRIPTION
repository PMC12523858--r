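Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Analysis of First-Line
    Sugemalimab Plus CAPOX in Advanced Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (progression-free, progressed, dead) partitioned
    survival model for the cost-effectiveness of adding the PD-L1 inhibitor
    sugemalimab to capecitabine plus oxaliplatin (CAPOX) as first-line
    treatment of advanced gastric or gastroesophageal-junction
    adenocarcinoma, from the perspective of Taiwan's single-payer National
    Health Insurance. Includes parametric survival extrapolation over seven
    distribution families, Guyot-style reconstruction of pseudo individual
    patient data from digitized Kaplan-Meier curves, discounted cost and
    QALY accrual with a point-based fee-schedule conversion, deterministic
    (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and expected value of perfect
    information, a declarative scenario grid, and value-based price
    threshold solving.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
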