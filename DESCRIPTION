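Package: mashboard
Title: Multi-Source County Data Fusion and Crossfilter-Style Querying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests per-county marginal datasets (category counts for
    qualitative variables, county or state means for quantitative ones),
    fuses them into a privacy-preserving synthetic population of weighted
    samples at a configurable scale (one sample per 1,000 persons by
    default), and interrogates the fused pool through a crossfilter-style
    shared filter engine, a URL query-string grammar, cohort-based
    anchoring for location-free datasets, and filtered CSV export.
    Includes deterministic fixture generators so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
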