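# Format reading, type inference, and configuration suggestion.

test_that("type inference follows the documented precedence", {
  expect_equal(infer_column_type(c("1", "2", "-3"))$kind, "integer")
  flt <- infer_column_type(c("1.5", "2e-3", ""))
  expect_equal(flt$kind, "float")
  expect_true(flt$has_missing)
  expect_equal(infer_column_type(c("True", "false"))$kind, "boolean_like")
  expect_equal(infer_column_type(c("chr1", "chr2"))$kind, "nominal")
  # NA-like tokens and gene symbols stay nominal; 0/1 stays integer
  expect_equal(infer_column_type(c("NA", "NaN"))$kind, "nominal")
  expect_equal(infer_column_type(c("0", "1", "1"))$kind, "integer")
  expect_equal(infer_column_type(c("SEPT2", "MARCH1"))$kind, "nominal")
})

test_that("type inference is permutation- and duplication-invariant", {
  set.seed(7)
  pools <- list(c("1", "2", ""), c("x", "y", "1.5"), c("true", "FALSE"),
                c("7e3", "-1", "2.5"))
  for (pool in pools) {
    base <- infer_column_type(pool)
    shuffled <- infer_column_type(sample(pool))
    doubled <- infer_column_type(rep(pool, 2))
    expect_equal(shuffled$kind, base$kind)
    expect_equal(doubled$kind, base$kind)
    expect_equal(shuffled$observed_min, base$observed_min)
    expect_equal(doubled$observed_max, base$observed_max)
  }
})

test_that("the same data reads identically from all four formats", {
  dir <- withr::local_tempdir()
  tab <- tibble::tibble(a = c(1L, 2L), b = c("x", "y"), c = c(0.5, NA))
  readr::write_csv(tab, file.path(dir, "t.csv"), na = "")
  readr::write_tsv(tab, file.path(dir, "t.tsv"), na = "")
  arrow::write_parquet(tab, file.path(dir, "t.parquet"))
  jsonlite::write_json(tab, file.path(dir, "t.json"), dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  from_csv <- read_table(file.path(dir, "t.csv"))
  for (f in c("t.tsv", "t.parquet", "t.json")) {
    expect_equal(as.data.frame(read_table(file.path(dir, f))),
                 as.data.frame(from_csv), label = f)
  }
  expect_equal(as.data.frame(from_csv), as.data.frame(tab))
})

test_that("minimal CSV parses with typed cells", {
  dir <- withr::local_tempdir()
  writeLines("a,b\n1,x", file.path(dir, "m.csv"))
  tab <- read_table(file.path(dir, "m.csv"))
  expect_equal(names(tab), c("a", "b"))
  expect_identical(tab$a, 1L)
  expect_identical(tab$b, "x")
})

test_that("read errors name the problem", {
  dir <- withr::local_tempdir()
  expect_error(read_table(file.path(dir, "absent.csv")),
               class = "tabreport_io_error")
  writeLines(c("a,b", "1,x,surplus"), file.path(dir, "bad.csv"))
  expect_error(read_table(file.path(dir, "bad.csv")), "row 2")  # file line number
  writeLines('[{"a": {"nested": 1}}]', file.path(dir, "nested.json"))
  expect_error(read_table(file.path(dir, "nested.json")),
               class = "tabreport_io_error")
})

test_that("JSON arrays of flat objects take the union of keys as columns", {
  dir <- withr::local_tempdir()
  writeLines('[{"a": 1, "b": "x"}, {"a": 2, "c": true}]',
             file.path(dir, "u.json"))
  tab <- read_table(file.path(dir, "u.json"))
  expect_equal(names(tab), c("a", "b", "c"))
  expect_identical(tab$b, c("x", NA))
  expect_identical(tab$c, c(NA, TRUE))
})

test_that("suggestions pick renderers from the inference rules", {
  tab <- tibble::tibble(
    frac = c(0, 0.4, 1),
    group = c("a", "b", "a"),
    many = sprintf("v%02d", 1:3),
    flag = c("true", "false", "true"),
    const = c(5, 5, 5)
  )
  # force 'many' above the categorical cutoff
  tab <- tab[rep(1:3, 11), ]
  tab$many <- sprintf("v%02d", seq_len(nrow(tab)))
  yaml_text <- suggest_config(list(main = tab))
  config <- load_config(yaml_text)
  cols <- config$views$main$columns
  expect_equal(cols$frac$renderer$kind, "heatmap")
  expect_equal(cols$frac$renderer$scale$kind, "linear")
  expect_equal(cols$frac$renderer$scale$domain, c(0, 1))
  expect_equal(cols$group$renderer$scale$kind, "categorical")
  expect_equal(cols$many$renderer$kind, "plain")       # > 12 distinct
  expect_equal(cols$const$renderer$kind, "plain")      # degenerate range
  expect_equal(cols$flag$renderer$kind, "custom_script")  # boolean spell
  expect_equal(cols$flag$spell$identifier, "boolean")
})

test_that("suggest output validates with zero issues on random fixtures", {
  for (seed in 1:5) {
    tab <- simulate_mixed_table(n_rows = 80, seed = seed)
    config <- load_config(suggest_config(list(fixture = tab)))
    issues <- validate_config(config, list(fixture = tab))
    expect_equal(nrow(issues), 0L)
  }
  expect_error(suggest_config(list(empty = tibble::tibble())),
               class = "tabreport_config_error")
})
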