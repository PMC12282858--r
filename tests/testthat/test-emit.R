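# Bundle assembly, self-containment, XLSX export, share URLs, QR codes.

test_that("a partitioned view emits the page/payload/index file equation", {
  dir <- withr::local_tempdir()
  tab <- tibble::tibble(k = seq_len(4500),
                        g = sample(letters[1:5], 4500, replace = TRUE))
  proj <- write_project(tab, dir,
                        config = paste(
                          "default_page_size: 2000",
                          "datasets: {main: {path: main.csv}}",
                          "views: {main: {dataset: main, columns: {k: ~}}}",
                          sep = "\n"))
  out <- file.path(proj, "report")
  bundle <- generate_report(file.path(proj, "config.yaml"), out)
  files <- bundle$manifest$file
  # ceil(4500/2000) = 3 pages, 3 payloads, 2 index documents
  expect_equal(sum(grepl("^main/page_\\d+\\.html$", files)), 3L)
  expect_equal(sum(grepl("^data/main/\\d+\\.js$", files)), 3L)
  expect_equal(sum(grepl("^main/index_", files)), 2L)
  expect_true("index.html" %in% files)
  expect_true(all(file.exists(file.path(out, files))))
  # every manifest file exists and every file on disk is in the manifest
  on_disk <- list.files(out, recursive = TRUE)
  expect_setequal(on_disk, files)
})

test_that("emitted bundles carry no external references", {
  dir <- withr::local_tempdir()
  make_fixtures(dir, seed = 5, n_genes = 30, n_variants = 60)
  out <- file.path(dir, "report")
  expect_equal(cmd_generate(file.path(dir, "config.yaml"), out), 0L)
  refs <- scan_external_refs(out)
  expect_equal(nrow(refs), 0L)
  # static assets exist and are referenced only relatively
  expect_true(file.exists(file.path(out, "static", "report.js")))
  expect_true(file.exists(file.path(out, "static", "report.css")))
  # the scanner itself notices planted external references
  writeLines('<html><script src="https://cdn.example/x.js"></script></html>',
             file.path(out, "planted.html"))
  expect_equal(nrow(scan_external_refs(out)), 1L)
})

test_that("two builds of the same input are byte-identical", {
  dir <- withr::local_tempdir()
  make_fixtures(dir, seed = 11, n_genes = 15, n_variants = 30)
  config <- load_config(file.path(dir, "config.yaml"))
  tabs <- lapply(config$datasets, function(ds) {
    ds$path <- file.path(dir, ds$path)
    read_table(ds)
  })
  out1 <- file.path(dir, "r1")
  out2 <- file.path(dir, "r2")
  render_report(config, tabs, out1)
  render_report(config, tabs, out2)
  files <- list.files(out1, recursive = TRUE)
  expect_setequal(files, list.files(out2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(out1, f), "raw",
                             file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw",
                             file.size(file.path(out2, f))),
                     label = f)
  }
})

test_that("page payloads decompress to exactly the emitted row slice", {
  dir <- withr::local_tempdir()
  tab <- tibble::tibble(idx = seq_len(250), w = sprintf("w%03d", 250:1))
  proj <- write_project(tab, dir, config = paste(
    "default_page_size: 100",
    "datasets: {main: {path: main.csv}}",
    "views: {main: {dataset: main, columns: {idx: ~}}}",
    sep = "\n"))
  out <- file.path(proj, "report")
  generate_report(file.path(proj, "config.yaml"), out)
  for (k in 1:3) {
    js <- paste(readLines(file.path(out, sprintf("data/main/%d.js", k)),
                          warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    payload <- sub('.*= "', "", js)
    payload <- sub('";\\s*$', "", payload)
    payload <- gsub("\\u2028", intToUtf8(0x2028), payload, fixed = TRUE)
    payload <- gsub("\\u2029", intToUtf8(0x2029), payload, fixed = TRUE)
    payload <- gsub('\\"', '"', payload, fixed = TRUE)
    payload <- gsub("\\\\", "\\", payload, fixed = TRUE)
    got <- unpack_table(tabreport:::json_to_packed(
      lz_decompress(payload, alphabet = "utf16_safe")))
    want <- tab[((k - 1) * 100 + 1):min(250, k * 100), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("XLSX export preserves identifiers as text and numbers as numbers", {
  skip_if_not_installed("readxl")
  dir <- withr::local_tempdir()
  genes <- simulate_report_tables(n_genes = 21, n_variants = 10,
                                  seed = 2)$genes
  path <- file.path(dir, "wb.xlsx")
  export_xlsx(list(genes = genes, extra = tibble::tibble(v = 3.5)), path)
  expect_equal(readxl::excel_sheets(path), c("genes", "extra"))
  back <- readxl::read_xlsx(path, sheet = "genes")
  # all 21 gene-like identifiers survive as text (SEPT2 not a date)
  expect_identical(back$gene, genes$gene)
  expect_true(is.character(back$gene))
  expect_identical(back$gene[1], "SEPT2")
  expect_true(is.numeric(back$score))
  extra <- readxl::read_xlsx(path, sheet = "extra")
  expect_equal(extra$v, 3.5)
  # full cell-for-cell round trip
  expect_equal(as.data.frame(back),
               as.data.frame(genes), tolerance = 1e-12)
})

test_that("sheet name collisions resolve by numeric suffix", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.xlsx")
  long <- strrep("samename", 8)
  export_xlsx(stats::setNames(list(tiny_table(), tiny_table()),
                              c(long, paste0(long, "x"))), path)
  sheets <- readxl::excel_sheets(path)
  expect_equal(length(unique(sheets)), 2L)
})

canonical_text_row_chr <- function(row) {
  vapply(as.list(row), function(v) canonical_text(v), character(1))
}

test_that("share URLs round-trip a row through the URI alphabet", {
  row <- tiny_table()[2, ]
  url <- encode_share_url(row, base_url = "https://intranet.example/view")
  expect_match(url, "^https://intranet\\.example/view\\?row=")
  payload <- sub(".*row=", "", url)
  expect_match(payload, "^[A-Za-z0-9+$-]*$")
  back <- decode_share_url(url)
  expect_equal(back, c(gene = "TP53", score = "0.5", hits = "0",
                       flag = "false"))
  # random rows round-trip
  for (seed in 1:10) {
    tab <- random_table(3, seed = seed)
    u <- encode_share_url(tab[1, ])
    expect_equal(unname(decode_share_url(u)),
                 unname(canonical_text_row_chr(tab[1, ])))
  }
})

test_that("QR codes decode back to their URL via an independent reader", {
  url <- encode_share_url(tiny_table()[1, ],
                          base_url = "https://viewer.example/share")
  dir <- withr::local_tempdir()
  qm <- make_qr(url, file.path(dir, "row.png"))
  expect_true(file.exists(file.path(dir, "row.png")))
  expect_identical(qr_reader_decode(qm), url)
  # SVG output and degenerate payload
  make_qr("https://viewer.example/share?row=", file.path(dir, "base.svg"))
  expect_match(readLines(file.path(dir, "base.svg"), warn = FALSE)[1],
               "^<svg")
  # oversized payload: capacity error
  wide <- stats::setNames(as.list(sprintf("text%04d", 1:120)),
                          sprintf("col%04d", 1:120))
  expect_error(make_qr(encode_share_url(wide), file.path(dir, "big.png")),
               class = "tabreport_capacity_error")
})

test_that("markdown and math render into view descriptions", {
  dir <- withr::local_tempdir()
  proj <- write_project(tiny_table(), dir, config = paste(
    "datasets: {main: {path: main.csv}}",
    "views:",
    "  main:",
    "    dataset: main",
    "    description: 'Scores are **normalized**; $p < 0.05$ is starred.'",
    "    columns: {gene: ~}",
    sep = "\n"))
  out <- file.path(proj, "report")
  generate_report(file.path(proj, "config.yaml"), out)
  page <- paste(readLines(file.path(out, "main/page_1.html"), warn = FALSE,
                          encoding = "UTF-8"), collapse = "\n")
  expect_match(page, "<strong>normalized</strong>")
  expect_match(page, "<span class=\"math\">p &lt; 0.05</span>", fixed = TRUE)
})
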