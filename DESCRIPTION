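Package: ecamiss
Title: Longitudinal Missing-Data Approaches for External Control Arm Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing approaches to longitudinal missing outcome
    data when a prospective observational cohort serves as the external
    control arm for a single-arm clinical trial. Implements the DAS28-ESR
    remission endpoint, classification of per-visit missingness into
    missing-at-visit, intermittent and drop-out types, propensity-score
    inverse probability of treatment weighting, artificial censoring with
    time-varying inverse probability of censoring weights, multiple
    imputation by chained equations with predictive mean matching and
    Rubin's-rule pooling, and an orchestrator that runs five analysis
    strategies (complete follow-up case, strict censoring + IPCW,
    MI + censoring + IPCW, MI + IPCW, MI for all) end to end. A synthetic
    two-cohort generator with known ground truth emulates trial-like
    monotone drop-out and observational-style non-monotone missingness
    under MCAR, MAR and delta-shifted MNAR mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    lmtest,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
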