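Package: gestwear
Title: Multimodal Wearable Biometrics Across Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of multimodal wearable-device physiology (distal body
    temperature, heart rate, heart rate variability, respiratory rate,
    activity) across the whole of pregnancy.  Provides sample-stream
    cleaning and daily aggregation (quantile filtering, activity-based
    non-wear gating, sleep annotation, peak/trough band statistics),
    pregnancy alignment and cohort eligibility filtering, baseline
    z-scoring and population trajectory profiles with rank-based trimester
    tests, a cumulative multimodal distance statistic with leave-one-out
    referencing, a time-matched generalized estimating equation analysis of
    early fetal loss, and a seeded synthetic-cohort simulator so that every
    stage is testable without access to proprietary wearable data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    arrow,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
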