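# Pagination of large tables and pre-built per-column search indices mapping
# canonical cell values to their (page, row offset) occurrences.

#' Choose between in-memory and partitioned mode
#'
#' A view is partitioned iff its row count strictly exceeds the threshold
#' (default 20000 rows); otherwise the whole table is embedded in one page
#' and filtered in memory.
#'
#' @param row_count Number of rows.
#' @param threshold Partition threshold (rows).
#' @return `"in_memory"` or `"partitioned"`.
#' @export
choose_mode <- function(row_count, threshold = default_page_size()) {
  stopifnot(is_count(threshold))
  stopifnot(is.numeric(row_count), length(row_count) == 1, row_count >= 0)
  if (row_count > threshold) "partitioned" else "in_memory"
}

#' Split a table into pages
#'
#' Produces `ceiling(n / page_size)` contiguous pages in order; all but the
#' last hold exactly `page_size` rows. An empty table yields one empty page.
#'
#' @param table A data frame.
#' @param page_size Rows per page (>= 1).
#' @return A list of pages; each page is a list with `page_number` (1-based),
#'   `start` (1-based absolute index of its first row), and `rows` (the
#'   slice as a tibble).
#' @export
paginate <- function(table, page_size = default_page_size()) {
  table <- as_report_table(table)
  stopifnot(is_count(page_size))
  page_size <- as.integer(page_size)
  n <- nrow(table)
  n_pages <- max(1L, as.integer(ceiling(n / page_size)))
  lapply(seq_len(n_pages), function(k) {
    start <- (k - 1L) * page_size + 1L
    end <- min(n, k * page_size)
    rows <- if (start > end) table[0, , drop = FALSE]
            else table[start:end, , drop = FALSE]
    list(page_number = k, start = start, rows = rows)
  })
}

# (page, offset) coordinates of absolute row indices under a page size.
page_coords <- function(rows, page_size) {
  page_size <- as.integer(page_size)
  list(page = ((rows - 1L) %/% page_size) + 1L,
       offset = (rows - 1L) %% page_size)
}

#' Build per-column search indices
#'
#' For every column, maps each canonical cell text to the ordered list of its
#' occurrences as (page number, row offset within page) under the given
#' pagination. Every cell of the table appears in the index (completeness)
#' and every index entry points at an equal cell (soundness).
#'
#' @param table A data frame.
#' @param page_size Rows per page used for the coordinates (must match the
#'   pagination of the emitted view).
#' @return A named list (one element per column); each element is a tibble
#'   with columns `value`, `page`, `offset`, sorted by (page, offset) within
#'   each value and listing values in first-occurrence order.
#' @export
build_search_index <- function(table, page_size = default_page_size()) {
  table <- as_report_table(table)
  stopifnot(is_count(page_size))
  n <- nrow(table)
  coords <- page_coords(seq_len(max(n, 1L))[seq_len(n)], page_size)
  out <- lapply(names(table), function(cn) {
    value <- canonical_text(table[[cn]])
    idx <- tibble(value = value,
                  page = as.integer(coords$page),
                  offset = as.integer(coords$offset))
    # Row order is already (page, offset) order; group values by first
    # occurrence without reordering occurrences.
    idx[order(match(idx$value, unique(idx$value))), , drop = FALSE]
  })
  names(out) <- names(table)
  out
}

#' Plan the emission of per-column index documents
#'
#' One self-contained index document per column, so that opening one
#' column's index never loads the others into memory. Each document carries
#' its column's index as a compressed payload.
#'
#' @param index A search index from [build_search_index()].
#' @param view_id View id the documents belong to.
#' @return A tibble with columns `column`, `file` (the index document's
#'   path), and `payload` (list-column of `compressed_blob`s).
#' @export
plan_index_pages <- function(index, view_id = "view") {
  columns <- names(index)
  files <- sprintf("%s/index_%s.html", slugify(view_id), slugify(columns))
  payloads <- lapply(columns, function(cn) {
    lz_compress(index_to_json(index[[cn]], cn), "utf16_safe")
  })
  tibble(column = columns, file = files, payload = payloads)
}

# Index JSON wire form: values in first-occurrence order with their
# occurrence coordinate lists.
index_to_json <- function(column_index, column_name) {
  values <- unique(column_index$value)
  groups <- split(seq_len(nrow(column_index)),
                  factor(column_index$value, levels = values))
  occ <- lapply(groups, function(ix) {
    unname(Map(c, column_index$page[ix], column_index$offset[ix]))
  })
  names(occ) <- NULL
  doc <- list(v = 1L, column = column_name, values = values, occurrences = occ)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

json_to_index <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  values <- vapply(doc$values, as.character, character(1))
  rows <- list()
  for (i in seq_along(values)) {
    for (hit in doc$occurrences[[i]]) {
      rows[[length(rows) + 1]] <- tibble(
        value = values[i],
        page = as.integer(hit[[1]]),
        offset = as.integer(hit[[2]])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(value = character(0), page = integer(0), offset = integer(0)))
  }
  bind_rows(rows)
}
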