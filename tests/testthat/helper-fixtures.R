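# Shared in-code fixtures for the suite.

tiny_table <- function() {
  tibble::tibble(
    gene = c("SEPT2", "TP53", "BRCA1"),
    score = c(0.1, 0.5, 0.9),
    hits = c(3L, 0L, 12L),
    flag = c(TRUE, FALSE, TRUE)
  )
}

# A random mixed-type tibble; NA cells sprinkled into nullable columns.
random_table <- function(n, seed, vocab = 20) {
  set.seed(seed)
  words <- replicate(vocab, paste(sample(letters, sample(3:8, 1),
                                         replace = TRUE), collapse = ""))
  tibble::tibble(
    label = sample(words, n, replace = TRUE),
    value = round(stats::rnorm(n), 4),
    count = sample.int(1000, n, replace = TRUE),
    ok = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    note = ifelse(stats::runif(n) < 0.1, NA_character_,
                  sample(words, n, replace = TRUE))
  )
}

minimal_config_yaml <- function(extra_columns = "") {
  paste0(
    "report_name: Test\n",
    "datasets:\n",
    "  main:\n",
    "    path: main.csv\n",
    "    format: csv\n",
    "views:\n",
    "  main:\n",
    "    dataset: main\n",
    "    columns:\n",
    "      gene: {label: Gene}\n",
    extra_columns
  )
}

# Write a one-dataset project (table + config) into a temp dir.
write_project <- function(table, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          config = minimal_config_yaml()) {
  readr::write_csv(table, file.path(dir, "main.csv"), na = "")
  writeLines(config, file.path(dir, "config.yaml"))
  dir
}
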