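# Seed-reproducible synthetic tables and projects used by tests, docs, and
# the acceptance checks. The tables emulate the mixed-type spreadsheets the
# generator is aimed at: gene-symbol-like identifiers (including SEPT2,
# which spreadsheet software famously auto-converts to a date), numeric
# scores and p-values, boolean flags, low- and high-cardinality nominal
# columns, and delimited multi-value cells.

GENE_SYMBOLS <- c(
  "SEPT2", "MARCH1", "DEC1", "TP53", "BRCA1", "BRCA2", "EGFR", "KRAS",
  "MYC", "PTEN", "RB1", "APC", "VHL", "ATM", "NRAS", "BRAF", "ALK",
  "RET", "MET", "ERBB2", "CDKN2A"
)

#' Simulate linked report tables
#'
#' Generates a `genes` overview table and a `variants` detail table whose
#' `gene` column is a foreign key into `genes` (which holds each symbol
#' exactly once, so primary-key uniqueness holds by construction). Output is
#' deterministic for a given seed.
#'
#' @param n_genes Number of gene rows.
#' @param n_variants Number of variant rows.
#' @param seed Random seed; all randomness flows through it.
#' @param missing_rate Fraction of cells blanked out in nullable columns.
#' @return A named list of tibbles: `genes`, `variants`.
#' @export
simulate_report_tables <- function(n_genes = 100, n_variants = 400,
                                   seed = 1, missing_rate = 0.02) {
  stopifnot(n_genes >= 1, n_variants >= 0)
  set.seed(seed)
  symbols <- c(GENE_SYMBOLS,
               sprintf("GENE%04d", seq_len(max(0, n_genes - length(GENE_SYMBOLS)))))
  symbols <- symbols[seq_len(n_genes)]

  keywords_pool <- c("kinase", "tumor-suppressor", "oncogene", "membrane",
                     "nuclear", "secreted", "transcription", "repair")
  categories <- c("driver", "passenger", "unknown")
  blank <- function(x) {
    x[stats::runif(length(x)) < missing_rate] <- NA
    x
  }

  genes <- tibble(
    gene = symbols,
    score = round(stats::runif(n_genes), 4),
    log2fc = round(stats::rnorm(n_genes, sd = 2), 3),
    se = round(stats::runif(n_genes, 0.05, 0.8), 3),
    p_value = signif(10^stats::runif(n_genes, -9, 0), 3),
    n_samples = sample(3:500, n_genes, replace = TRUE),
    significant = stats::runif(n_genes) < 0.3,
    category = blank(sample(categories, n_genes, replace = TRUE)),
    keywords = vapply(seq_len(n_genes), function(i) {
      paste(sample(keywords_pool, sample(1:4, 1)), collapse = ";")
    }, character(1)),
    summary = blank(vapply(seq_len(n_genes), function(i) {
      paste(sample(c("regulates", "cell", "cycle", "growth", "pathway",
                     "signal", "binding", "protein", "complex", "membrane",
                     "division", "stress", "response"),
                   sample(6:18, 1), replace = TRUE), collapse = " ")
    }, character(1)))
  )
  genes <- dplyr::mutate(genes,
    log2fc_lo = round(log2fc - 1.96 * se, 3),
    log2fc_hi = round(log2fc + 1.96 * se, 3),
    .after = "se"
  )

  variants <- tibble(
    id = sprintf("var%05d", seq_len(n_variants)),
    gene = sample(symbols, n_variants, replace = TRUE),
    chrom = sample(sprintf("chr%s", c(1:22, "X", "Y")), n_variants,
                   replace = TRUE),
    pos = sample.int(2.5e8, n_variants, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
    qual = round(stats::runif(n_variants, 0, 60), 1),
    af = signif(stats::runif(n_variants), 3),
    consequence = sample(c("missense", "synonymous", "stop_gained",
                           "splice", "intron"), n_variants, replace = TRUE)
  )
  list(genes = genes, variants = variants)
}

#' Simulate one wide mixed-type table
#'
#' A single flat table combining every column kind the type-inference and
#' suggestion rules distinguish; used by property tests and the closure
#' checks.
#'
#' @param n_rows Number of rows.
#' @param seed Random seed.
#' @return A tibble.
#' @export
simulate_mixed_table <- function(n_rows = 1000, seed = 1) {
  set.seed(seed)
  n <- n_rows
  tibble(
    id = sprintf("row%06d", seq_len(n)),
    gene = sample(GENE_SYMBOLS, n, replace = TRUE),
    count = sample.int(10000, n, replace = TRUE),
    ratio = round(stats::runif(n), 6),
    flag = sample(c("true", "false"), n, replace = TRUE),
    group = sample(sprintf("group_%d", 1:6), n, replace = TRUE),
    free_text = vapply(seq_len(n), function(i) {
      paste(sample(letters, sample(5:30, 1), replace = TRUE), collapse = "")
    }, character(1)),
    tags = vapply(seq_len(n), function(i) {
      paste(sample(c("a", "b", "c", "d"), sample(1:3, 1)), collapse = ",")
    }, character(1))
  )
}

#' Write a complete fixture project to disk
#'
#' Writes the simulated tables in all four supported input formats plus a
#' configuration that exercises linking, spells, and every built-in
#' renderer. The same seed always produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Random seed.
#' @param n_genes,n_variants Table sizes.
#' @return The configuration file path, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, n_genes = 100, n_variants = 400) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- simulate_report_tables(n_genes = n_genes, n_variants = n_variants,
                                 seed = seed)
  readr::write_csv(tabs$genes, file.path(dir, "genes.csv"), na = "")
  readr::write_tsv(tabs$genes, file.path(dir, "genes.tsv"), na = "")
  arrow::write_parquet(tabs$genes, file.path(dir, "genes.parquet"))
  jsonlite::write_json(tabs$genes, file.path(dir, "genes.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  readr::write_tsv(tabs$variants, file.path(dir, "variants.tsv"), na = "")

  config <- fixture_config_yaml()
  writeLines(config, file.path(dir, "config.yaml"), useBytes = TRUE)
  invisible(file.path(dir, "config.yaml"))
}

fixture_config_yaml <- function() {
  paste(
    'report_name: Gene panel report',
    'datasets:',
    '  genes:',
    '    path: genes.csv',
    '    format: csv',
    '    links:',
    '      variants for gene:',
    '        kind: subtable_link',
    '        source_column: gene',
    '        detail_dataset: variants',
    '  variants:',
    '    path: variants.tsv',
    '    format: tsv',
    '    links:',
    '      gene overview:',
    '        kind: row_link',
    '        source_column: gene',
    '        target_view: genes',
    '        target_key_column: gene',
    'views:',
    '  genes:',
    '    dataset: genes',
    '    description: "Per-gene summary statistics; $p$-values from the *upstream* analysis."',
    '    show_line_numbers: true',
    '    columns:',
    '      gene:',
    '        label: Gene',
    '        linkouts:',
    '          - name: NCBI',
    '            url_template: "https://www.ncbi.nlm.nih.gov/gene/?term={value}"',
    '      score:',
    '        renderer:',
    '          kind: heatmap',
    '          scale:',
    '            kind: linear',
    '            domain: [0, 1]',
    '            colors: ["#ffffff", "#4682b4"]',
    '      log2fc:',
    '        renderer:',
    '          kind: tick',
    '          domain: [-6, 6]',
    '          aux_range: [log2fc_lo, log2fc_hi]',
    '      se:',
    '        display_mode: hidden',
    '      p_value:',
    '        spell:',
    '          identifier: p-value',
    '          with: {threshold: 0.05}',
    '      n_samples:',
    '        renderer:',
    '          kind: bar',
    '          domain: [0, 500]',
    '          color_scale:',
    '            kind: linear',
    '            domain: [0, 500]',
    '            colors: ["#ffffff", "#2ca02c"]',
    '      significant:',
    '        spell:',
    '          identifier: boolean',
    '          with: {true_value: "true", false_value: "false"}',
    '      category:',
    '        renderer:',
    '          kind: heatmap',
    '          scale:',
    '            kind: categorical',
    '            domain: [driver, passenger, unknown]',
    '            colors:',
    '              driver: "#d62728"',
    '              passenger: "#1f77b4"',
    '              unknown: "#7f7f7f"',
    '      keywords:',
    '        renderer: {kind: pills, separator: ";"}',
    '      summary:',
    '        display_mode: detail',
    '        ellipsis_limit: 40',
    '  variants:',
    '    dataset: variants',
    '    description: Individual variant calls per gene.',
    '    columns:',
    '      gene: {label: Gene}',
    '      qual:',
    '        renderer:',
    '          kind: bar',
    '          domain: [0, 60]',
    '      af:',
    '        numeric_format: scientific',
    sep = "\n"
  )
}
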