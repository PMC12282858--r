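# Memoized packing and LZ-string compression.

test_that("pack_table builds a first-occurrence dictionary with 0-based codes", {
  tab <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"))
  packed <- pack_table(tab)
  expect_equal(packed$dict, c("chr1", "chr2"))
  expect_equal(packed$cols[[1]], c(0L, 0L, 1L))
  expect_false("chrom" %in% packed$dict)  # header stays out of the dict

  # row-major scan order across several text columns
  tab2 <- tibble::tibble(a = c("x", "z"), b = c("y", "x"))
  expect_equal(pack_table(tab2)$dict, c("x", "y", "z"))
})

test_that("packing an empty table yields an empty dictionary and no rows", {
  packed <- pack_table(tibble::tibble(a = character(0), b = numeric(0)))
  expect_equal(packed$dict, character(0))
  expect_equal(packed$n_rows, 0L)
  expect_equal(nrow(unpack_table(packed)), 0L)
})

test_that("dictionary size equals the brute-force distinct text-cell count", {
  for (seed in 1:20) {
    tab <- random_table(n = 60, seed = seed, vocab = 12)
    packed <- pack_table(tab)
    text_cells <- unlist(lapply(tab[vapply(tab, is.character, logical(1))],
                                identity))
    expect_equal(length(packed$dict),
                 length(unique(text_cells[!is.na(text_cells)])))
  }
})

test_that("unpack is the exact inverse of pack over random tables", {
  for (seed in 1:40) {
    tab <- random_table(n = sample.int(80, 1), seed = seed)
    expect_equal(unpack_table(pack_table(tab)), tab, ignore_attr = TRUE)
  }
  # JSON wire form round-trips too
  tab <- random_table(50, seed = 99)
  via_json <- unpack_table(tabreport:::json_to_packed(
    tabreport:::packed_to_json(pack_table(tab))))
  expect_equal(as.data.frame(via_json), as.data.frame(tab))
})

test_that("out-of-range dictionary indices raise a corruption error", {
  packed <- pack_table(tibble::tibble(a = c("x", "y")))
  packed$cols[[1]][2] <- 2L  # == len(dict): out of range
  expect_error(unpack_table(packed), class = "tabreport_corruption_error")
})

test_that("lz round trip is exact for unicode text in both alphabets", {
  cases <- c("", "a", "hello hello hello", strrep("ab", 200),
             "tabs\tand\nnewlines", "quotes \" and \\ slashes",
             "café naïve 世界 \U0001F600")
  for (s in cases) {
    for (alpha in c("utf16_safe", "uri_component")) {
      blob <- lz_compress(s, alpha)
      expect_identical(lz_decompress(blob), s)
    }
  }
})

test_that("uri_component payloads stay within the URL-safe alphabet", {
  for (seed in 1:10) {
    set.seed(seed)
    s <- paste(sample(c(letters, " ", "ü", "#", "&", "?"), 120,
                      replace = TRUE), collapse = "")
    payload <- lz_compress(s, "uri_component")$payload
    expect_match(payload, "^[A-Za-z0-9+$-]*$")
  }
})

test_that("codec agrees with an independent reference implementation", {
  set.seed(2024)
  pool <- c(letters, LETTERS, 0:9, " ", ",", ";", "é", "中", "\"")
  for (i in 1:40) {
    s <- paste(sample(pool, sample(0:60, 1), replace = TRUE), collapse = "")
    # identical compressed words in both directions, both alphabets
    expect_identical(lz_compress(s, "utf16_safe")$payload,
                     ref_lz_compress_utf16(s))
    expect_identical(lz_compress(s, "uri_component")$payload,
                     ref_lz_compress_uri(s))
    # cross-decompression: each side decodes the other's payloads
    expect_identical(ref_lz_decompress_utf16(lz_compress(s)$payload), s)
    expect_identical(
      lz_decompress(ref_lz_compress_uri(s), alphabet = "uri_component"), s)
  }
  # known vector: the empty string compresses to "Q" in the URI alphabet
  expect_identical(lz_compress("", "uri_component")$payload, "Q")
})

test_that("undecodable payloads raise a corruption error", {
  expect_error(lz_decompress("!!not in alphabet!!", alphabet = "uri_component"),
               class = "tabreport_corruption_error")
})

test_that("identical input yields byte-identical payloads across runs", {
  tab <- random_table(100, seed = 5)
  p1 <- tabreport:::compress_table_payload(tab)$payload
  p2 <- tabreport:::compress_table_payload(tab)$payload
  expect_identical(p1, p2)
})

test_that("repetitive tables compress below their raw CSV size", {
  tab <- random_table(10000, seed = 11, vocab = 20)
  report <- compression_report(tab)
  raw <- report$bytes[report$serialization == "raw_csv"]
  compressed <- report$bytes[report$serialization == "compressed"]
  expect_lt(compressed, raw)
  # single-cell table: the report is still produced
  expect_equal(nrow(compression_report(tibble::tibble(a = "x"))), 3L)
})

test_that("whole-table compression beats per-page compression at small pages", {
  tab <- random_table(5000, seed = 21, vocab = 20)
  report <- compression_report(tab, page_sizes = 100)
  whole <- report$ratio[report$serialization == "compressed"]
  paged <- report$ratio[report$serialization == "compressed_pages_100"]
  expect_gte(whole, paged)
})
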