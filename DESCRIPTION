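Package: lysisgate
Title: Rule-Based Screening of Shared Electronic Health Records for Stroke Thrombolysis Contraindications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable clinical decision support engine for intravenous
    stroke thrombolysis. Screens multi-hospital electronic health record
    extracts against a declarative catalog of treatment contraindications
    with temporal lookback windows, consent-gated record sharing, a daily
    precomputed snapshot database merged with a live 24-hour refresh, and
    full evidence provenance per finding. Ships bedside calculators (NIHSS
    total score, weight-based tPA dose), a synthetic EHR generator for
    mock cases and randomized multi-hospital cohorts, and the analysis
    machinery for a counterbalanced two-period crossover evaluation
    (arm summaries, pooled t, exact Mann-Whitney, chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
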