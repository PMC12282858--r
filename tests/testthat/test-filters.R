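# Reference semantics of the in-memory filter mode.

test_that("an empty filter state keeps every row", {
  tab <- random_table(50, seed = 1)
  expect_equal(apply_filters(tab), tab, ignore_attr = TRUE)
  expect_equal(apply_filters(tab, list(label = list(kind = "any"))), tab,
               ignore_attr = TRUE)
})

test_that("predicates combine as set intersection across columns", {
  tab <- random_table(200, seed = 2)
  s1 <- list(value = list(kind = "interval", lo = -0.5, hi = NULL))
  s2 <- list(label = list(kind = "keyword", keyword = "a"))
  both <- apply_filters(tab, c(s1, s2))
  left <- apply_filters(tab, s1)
  right <- apply_filters(tab, s2)
  expect_equal(as.data.frame(both),
               as.data.frame(dplyr::intersect(left, right)))
  # order of predicate application never matters
  expect_equal(apply_filters(tab, c(s2, s1)), both, ignore_attr = TRUE)
})

test_that("missing cells fail every active predicate", {
  tab <- tibble::tibble(x = c("a", NA, "b"), y = c(1, 2, NA))
  expect_equal(nrow(apply_filters(tab, list(x = list(kind = "keyword",
                                                     keyword = "")))), 2L)
  expect_equal(nrow(apply_filters(tab, list(y = list(kind = "interval",
                                                     lo = NULL, hi = NULL)))),
               2L)
})

test_that("filtering equals brute-force row-wise evaluation on random states", {
  # independent oracle: literal per-row predicate interpreter
  brute_row <- function(row, state) {
    for (cn in names(state)) {
      pred <- state[[cn]]
      if (is.null(pred) || pred$kind == "any") next
      v <- row[[cn]]
      if (is.na(v) || (is.character(v) && v == "")) return(FALSE)
      hit <- switch(pred$kind,
        values = canonical_text(v) %in% pred$values,
        keyword = grepl(tolower(pred$keyword), tolower(canonical_text(v)),
                        fixed = TRUE),
        interval = is.numeric(v) &&
          (is.null(pred$lo) || v >= pred$lo) &&
          (is.null(pred$hi) || v <= pred$hi)
      )
      if (!hit) return(FALSE)
    }
    TRUE
  }
  tab <- random_table(300, seed = 9)
  set.seed(99)
  for (trial in 1:50) {
    state <- list()
    if (stats::runif(1) < 0.7) {
      state$value <- list(kind = "interval",
                          lo = if (stats::runif(1) < 0.8) stats::rnorm(1),
                          hi = if (stats::runif(1) < 0.8) stats::rnorm(1))
    }
    if (stats::runif(1) < 0.7) {
      state$label <- list(kind = "values",
                          values = sample(unique(tab$label),
                                          sample(1:4, 1)))
    }
    if (stats::runif(1) < 0.5) {
      state$note <- list(kind = "keyword",
                         keyword = paste(sample(letters, 2), collapse = ""))
    }
    got <- apply_filters(tab, state)
    want <- tab[vapply(seq_len(nrow(tab)), function(i) {
      brute_row(as.list(tab[i, ]), state)
    }, logical(1)), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("widget kinds follow column type and cardinality", {
  expect_equal(filter_widget_kind(c(1.5, 2)), "interval")
  expect_equal(filter_widget_kind(letters[1:12]), "values")
  expect_equal(filter_widget_kind(sprintf("v%02d", 1:13)), "keyword")
  expect_equal(categorical_cutoff(), 12L)
})
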