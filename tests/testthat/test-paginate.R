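# Mode choice, pagination arithmetic, search indices.

test_that("mode choice is strict-greater on the threshold, default 20000", {
  expect_equal(choose_mode(100, 20000), "in_memory")
  expect_equal(choose_mode(20000, 20000), "in_memory")
  expect_equal(choose_mode(20001, 20000), "partitioned")
  expect_equal(default_page_size(), 20000L)
  expect_equal(choose_mode(20001), "partitioned")  # default threshold applies
})

test_that("pagination slices follow ceil(n / page_size) with ordered pages", {
  tab <- tibble::tibble(x = seq_len(45000))
  pages <- paginate(tab, 20000)
  expect_length(pages, 3)
  expect_equal(vapply(pages, function(p) nrow(p$rows), integer(1)),
               c(20000L, 20000L, 5000L))
  expect_length(paginate(tibble::tibble(x = 1:20000), 20000), 1)
  # empty table: one empty page
  empty <- paginate(tibble::tibble(x = integer(0)), 10)
  expect_length(empty, 1)
  expect_equal(nrow(empty[[1]]$rows), 0L)
})

test_that("concatenated pages reproduce the table for random sizes", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(0:200, 1)
    ps <- sample(1:50, 1)
    tab <- tibble::tibble(x = seq_len(n), y = sample(letters, n, TRUE))
    pages <- paginate(tab, ps)
    expect_length(pages, max(1, ceiling(n / ps)))
    sizes <- vapply(pages, function(p) nrow(p$rows), integer(1))
    if (n > 0) {
      expect_true(all(sizes[-length(sizes)] == ps))
      expect_equal(sum(sizes), n)
      # contiguous, ordered, covering
      expect_equal(vapply(pages, function(p) p$start, integer(1)),
                   cumsum(c(1L, sizes[-length(sizes)])))
    }
    glued <- dplyr::bind_rows(lapply(pages, function(p) p$rows))
    expect_equal(as.data.frame(glued), as.data.frame(tab))
  }
})

test_that("a single occurrence lands at its exact page and offset", {
  tab <- tibble::tibble(v = sprintf("val%02d", 1:30))
  tab$v[18] <- "needle"   # page 2, offset 7 at page size 10
  idx <- build_search_index(tab, page_size = 10)
  hit <- idx$v[idx$v$value == "needle", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$page, 2L)
  expect_equal(hit$offset, 7L)
})

test_that("indices are complete and sound against a brute-force scan", {
  for (seed in 1:8) {
    tab <- random_table(n = sample(50:150, 1), seed = seed, vocab = 10)
    ps <- sample(c(7, 20, 64), 1)
    idx <- build_search_index(tab, page_size = ps)
    for (cn in names(tab)) {
      canon <- canonical_text(tab[[cn]])
      entries <- idx[[cn]]
      # soundness: every entry points at an equal cell
      physical <- (entries$page - 1L) * ps + entries$offset + 1L
      expect_equal(canon[physical], entries$value)
      # completeness: every cell appears exactly once
      expect_equal(sort(physical), seq_len(nrow(tab)))
      # occurrences sorted by (page, offset) within each value
      for (v in unique(entries$value)) {
        occ <- entries[entries$value == v, ]
        expect_true(!is.unsorted(occ$page * (ps + 1) + occ$offset))
      }
    }
  }
})

test_that("index documents emit one per column and round-trip their payload", {
  tab <- random_table(40, seed = 3)
  idx <- build_search_index(tab, page_size = 10)
  plan <- plan_index_pages(idx, view_id = "view one")
  expect_equal(nrow(plan), ncol(tab))
  expect_equal(plan$file,
               sprintf("view%%20one/index_%s.html", names(tab)))
  for (i in seq_len(nrow(plan))) {
    json <- lz_decompress(plan$payload[[i]])
    back <- tabreport:::json_to_index(json)
    expect_equal(as.data.frame(back), as.data.frame(idx[[plan$column[i]]]))
  }
  # a 17-column table yields 17 index documents
  wide <- tibble::as_tibble(stats::setNames(as.list(1:17),
                                            sprintf("c%02d", 1:17)))
  expect_equal(nrow(plan_index_pages(build_search_index(wide, 5), "w")), 17L)
  # zero-row table: documents exist with empty value lists
  empty_idx <- build_search_index(tibble::tibble(a = character(0)), 5)
  empty_plan <- plan_index_pages(empty_idx, "e")
  expect_equal(nrow(empty_plan), 1L)
  expect_equal(nrow(tabreport:::json_to_index(
    lz_decompress(empty_plan$payload[[1]]))), 0L)
})
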