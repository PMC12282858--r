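Package: tabreport
Title: Portable Interactive HTML Reports from Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns tabular files (CSV, TSV, JSON, Parquet) plus a declarative
    YAML configuration into portable, self-contained, interactive HTML reports
    viewable in any browser without a web server. Supports per-cell
    visualizations (heatmaps, tick and bar plots, pill plots, ellipsis,
    linkouts), cross-table row linking via primary/foreign keys, hierarchical
    per-value subtables, memoized dictionary encoding plus LZ-string
    compression of embedded data payloads, partitioning of large tables into
    pages with pre-built per-column search indices, XLSX export that preserves
    identifiers as text, and per-row share URLs with QR codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    glue,
    stringr,
    readr,
    arrow,
    commonmark,
    ggplot2,
    png,
    utils,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    optparse
Config/testthat/edition: 3
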