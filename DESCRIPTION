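Package: actistep
Title: Wearable Activity and Inhalation-Behavior Endpoints for Pulmonary
    Hypertension Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for digitally monitored cohorts of patients
    with pulmonary arterial hypertension who track physical activity with a
    smartwatch while taking nebulized therapy. Ingests minute-resolution
    sensor epochs, nebulizer inhalation logs and clinical visit records;
    derives wear-time-normalized daily activity with a configurable
    missing-day rule; computes event-aligned post-inhalation activity
    curves, digital 6-minute-walk-distance and heart-rate endpoints
    (chronotropic response, recovery curves); and summarizes cohort-level
    change from baseline with pairwise-complete Pearson correlations and
    change-on-change regressions. A seeded synthetic-cohort generator with
    stored ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
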