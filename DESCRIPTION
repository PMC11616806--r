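Package: lvadcea
Title: Cost-Utility Modelling of Left Ventricular Assist Devices as
    Destination Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model comparing left
    ventricular assist devices (LVAD) as destination therapy with medical
    management in advanced heart failure, from a UK healthcare
    perspective.  Provides a monthly-cycle cohort engine with life-table
    background mortality and major-event states, discounted life-year,
    QALY and cost accumulation, incremental cost-effectiveness analysis
    with QALY-shortfall severity weighting, one-way deterministic
    (tornado) and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves, INTERMACS subgroup and
    bridge-to-transplant scenarios, and a calibrated synthetic parameter
    generator so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
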