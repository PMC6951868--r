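Package: sepscreen
Title: Rule-Based Sepsis Surveillance Screening, Simulation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A temporal rules engine for severe-sepsis surveillance over
    longitudinal clinical event streams, together with a synthetic
    electronic-health-record cohort generator and an evaluation layer.
    Encounters are screened for the conjunction of SIRS criteria and
    organ-dysfunction parameters within concept-specific lookback windows
    under configurable scenario presets (a CMS severe-sepsis style SEP-2
    scenario, the same scenario without the SBP-decrease parameter, and a
    conservative variant). Downstream analyses label suspected infection
    from microbiology cultures plus intravenous antibiotics, compute NEWS
    acuity and apparent strong ion difference at admission, and quantify
    the alert reliability / condition sensitivity trade-off, substitution
    effects between scenarios, and mortality risk by organ-system
    parameter via logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
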