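Package: sclccea
Title: Cost-Effectiveness Modelling of First-Line Immunochemotherapy in
    Extensive-Stage Small-Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-modelling pipeline for comparing first-line immune
    checkpoint inhibitor plus chemotherapy strategies against chemotherapy
    alone in extensive-stage small-cell lung cancer from a Chinese
    healthcare-system perspective.  Reconstructs pseudo individual patient
    data from digitized Kaplan-Meier coordinates and numbers at risk, fits
    and selects parametric survival distributions by AIC/BIC, extrapolates
    hazard-ratio-adjusted survival, simulates a three-state (progression-free,
    progressed, dead) cohort over 21-day cycles and a 20-year horizon,
    accumulates discounted costs and quality-adjusted life-years with
    anthropometric drug dosing and adverse-event burden, classifies the
    incremental cost-effectiveness frontier with strict and extended
    dominance, and runs deterministic (tornado, threshold) and probabilistic
    (Monte Carlo, acceptability-curve) sensitivity analyses, including
    subgroup-level runs.  Ships a synthetic-data module that generates every
    input needed to exercise the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
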