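# Primary keys, row-link resolution, hierarchical subtables.

make_link <- function(name = "jump", source = "gene", view = "target",
                      key = "gene", optional = FALSE) {
  list(name = name, kind = "row_link", source_column = source,
       target_view = view, target_key_column = key,
       detail_dataset = NULL, optional = optional)
}

test_that("primary key checks report exactly the duplicated values", {
  expect_true(check_primary_key(c("a", "b", "c"))$ok)
  dup <- check_primary_key(c("a", "a", "b"))
  expect_false(dup$ok)
  expect_equal(dup$duplicates, "a")
  # missing cells do not count as duplicates
  expect_true(check_primary_key(c("a", NA, "", "b", NA))$ok)
  # numeric/text cells compare canonically: 1 duplicates "1"
  expect_false(check_primary_key(list(c("1", "2", "1")) [[1]])$ok)
  keys <- sprintf("key%06d", 1:100000)
  expect_true(check_primary_key(keys)$ok)
})

test_that("row links resolve to the page/offset of the unique key match", {
  # BRCA1 placed so it lands on page 2, offset 7 at page size 10
  target <- tibble::tibble(gene = sprintf("G%03d", 1:30))
  target$gene[18] <- "BRCA1"
  source <- tibble::tibble(gene = c("BRCA1", "G001"))
  res <- resolve_row_links(source, list(make_link()),
                           list(target = target), list(target = 10L))
  hit <- res[res$row == 1, ]
  expect_equal(hit$target_view, "target")
  expect_equal(hit$page, 2L)
  expect_equal(hit$offset, 7L)
  expect_true(all(res$resolved))
})

test_that("optional links leave unmatched values unresolved; required abort", {
  target <- tibble::tibble(gene = c("TP53", "KRAS"))
  source <- tibble::tibble(gene = c("TP53", "GHOST", NA))
  res <- resolve_row_links(source, list(make_link(optional = TRUE)),
                           list(target = target), list(target = 100L))
  expect_equal(res$resolved, c(TRUE, FALSE, FALSE))
  expect_error(
    resolve_row_links(source, list(make_link()),
                      list(target = target), list(target = 100L)),
    "GHOST")
  # missing foreign keys never abort, even when the link is required
  just_missing <- tibble::tibble(gene = c("TP53", NA))
  res2 <- resolve_row_links(just_missing, list(make_link()),
                            list(target = target), list(target = 100L))
  expect_equal(res2$resolved, c(TRUE, FALSE))
})

test_that("duplicate primary keys abort naming the duplicated value", {
  target <- tibble::tibble(gene = c("TP53", "TP53"))
  source <- tibble::tibble(gene = "TP53")
  expect_error(
    resolve_row_links(source, list(make_link()),
                      list(target = target), list(target = 10L)),
    "TP53", class = "tabreport_key_error")
})

test_that("resolution equals a brute-force scan on randomized linked tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n_target <- sample(30:120, 1)
    page_size <- sample(c(3, 7, 10, 50), 1)
    target <- tibble::tibble(key = sample(sprintf("k%04d", 1:500), n_target))
    source <- tibble::tibble(key = sample(c(target$key, "absent"), 60,
                                          replace = TRUE))
    res <- resolve_row_links(
      source, list(make_link(source = "key", key = "key", optional = TRUE)),
      list(target = target), list(target = page_size))
    for (i in seq_len(nrow(source))) {
      brute <- which(target$key == source$key[i])
      row <- res[res$row == i, ]
      if (length(brute) == 0) {
        expect_false(row$resolved)
      } else {
        expect_equal(row$page, as.integer((brute - 1) %/% page_size + 1))
        expect_equal(row$offset, as.integer((brute - 1) %% page_size))
        # round trip: the targeted physical row carries the source's key
        physical <- (row$page - 1) * page_size + row$offset + 1
        expect_equal(target$key[physical], source$key[i])
      }
    }
  }
})

test_that("page size never changes which physical row a link targets", {
  set.seed(42)
  target <- tibble::tibble(key = sample(sprintf("k%03d", 1:80)))
  source <- tibble::tibble(key = sample(target$key, 25))
  physical_row <- function(page_size) {
    res <- resolve_row_links(
      source, list(make_link(source = "key", key = "key")),
      list(target = target), list(target = page_size))
    (res$page - 1L) * page_size + res$offset + 1L
  }
  expect_equal(physical_row(7L), physical_row(80L))
  expect_equal(physical_row(7L), physical_row(1L))
})

test_that("subtables partition the detail rows by key value", {
  parent <- tibble::tibble(gene = c("x", "y", "z"))
  detail <- tibble::tibble(gene = c("x", "x", "y"), v = 1:3)
  split <- split_subtables(parent, "gene", detail, view_id = "genes")
  expect_equal(vapply(split$table, nrow, integer(1)), c(2L, 1L, 0L))
  expect_equal(split$child_view, c("genes__x", "genes__y", "genes__z"))
  # multiset union of children equals the detail table
  all_children <- dplyr::bind_rows(split$table)
  expect_equal(dplyr::arrange(all_children, v),
               dplyr::arrange(detail, v))
  # children are disjoint: total rows match
  expect_equal(nrow(all_children), nrow(detail))
  expect_error(split_subtables(parent, "ghost", detail),
               class = "tabreport_link_error")
})

test_that("child view ids are deterministic slugs; collisions are errors", {
  parent <- tibble::tibble(k = c("a b", "a/b"))
  detail <- tibble::tibble(k = character(0))
  split <- split_subtables(parent, "k", detail, view_id = "v")
  expect_equal(split$child_view, c("v__a%20b", "v__a%2Fb"))
  collide <- tibble::tibble(k = c("a b", "a b "))  # hm: distinct keys
  split2 <- split_subtables(collide, "k", detail, view_id = "v")
  expect_equal(anyDuplicated(split2$child_view), 0L)
})
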