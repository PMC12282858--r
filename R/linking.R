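# Cross-dataset row links (foreign key -> unique primary key) and
# hierarchical per-value subtables. Key equality is exact on the canonical
# text form of cells (so the number 1 and the text "1" match across input
# formats); missing foreign keys always resolve to "unresolved".

#' Check a column for primary-key uniqueness
#'
#' A column can serve as a primary key only if every non-missing value is
#' distinct. The result is data, not an exception; report generation aborts
#' on duplicates for any column actually used as a primary key.
#'
#' @param values A vector of cells.
#' @return A list with `ok` (flag) and `duplicates` (character vector of
#'   duplicated canonical values, empty when ok).
#' @export
check_primary_key <- function(values) {
  keys <- canonical_text(values)
  keys <- keys[keys != ""]
  dup <- unique(keys[duplicated(keys)])
  list(ok = length(dup) == 0, duplicates = dup)
}

#' Resolve row links from a source table
#'
#' For every source row and every `row_link`, finds the unique target row
#' whose key column equals the source's foreign-key value, and expresses the
#' target as (view, page, offset) under the target view's pagination.
#' Missing foreign-key cells are always unresolved; a present value that has
#' no match aborts generation unless the link is `optional`.
#'
#' @param source Source table (a data frame).
#' @param links Named list of link specifications (`row_link`s are resolved,
#'   others ignored).
#' @param target_tables Named list: view id -> the target view's table.
#' @param target_page_sizes Named integer vector: view id -> rows per page of
#'   the target view.
#' @return A tibble with columns `row` (source row number), `link`,
#'   `target_view`, `page`, `offset` (0-based within page), `resolved`.
#' @export
resolve_row_links <- function(source, links, target_tables,
                              target_page_sizes) {
  source <- as_report_table(source, "source")
  out <- list()
  for (link in links) {
    if (link$kind != "row_link") next
    target <- target_tables[[link$target_view]]
    if (is.null(target)) {
      abort(glue("no table supplied for target view '{link$target_view}'"),
            class = "tabreport_type_error")
    }
    if (!link$source_column %in% names(source)) {
      abort(glue("link '{link$name}': source column '{link$source_column}' ",
                 "is absent"),
            class = "tabreport_link_error")
    }
    if (!link$target_key_column %in% names(target)) {
      abort(glue("link '{link$name}': target key column ",
                 "'{link$target_key_column}' is absent"),
            class = "tabreport_link_error")
    }
    keys <- canonical_text(target[[link$target_key_column]])
    pk <- check_primary_key(target[[link$target_key_column]])
    if (!pk$ok) {
      abort(glue("link '{link$name}': column '{link$target_key_column}' is ",
                 "not a primary key; duplicated value(s): ",
                 "{paste(utils::head(pk$duplicates, 5), collapse = ', ')}"),
            class = "tabreport_key_error")
    }
    fk <- canonical_text(source[[link$source_column]])
    target_row <- match(fk, keys)
    target_row[fk == ""] <- NA_integer_
    unmatched <- fk != "" & is.na(target_row)
    if (any(unmatched) && !link$optional) {
      abort(glue("link '{link$name}': value '{fk[unmatched][1]}' has no ",
                 "match in '{link$target_view}'"),
            class = "tabreport_link_error")
    }
    page_size <- target_page_sizes[[link$target_view]]
    stopifnot(is_count(page_size))
    page <- ((target_row - 1L) %/% as.integer(page_size)) + 1L
    offset <- (target_row - 1L) %% as.integer(page_size)
    link_name <- link$name
    view_id <- link$target_view
    out[[length(out) + 1]] <- tibble(
      row = seq_len(nrow(source)),
      link = link_name,
      target_view = view_id,
      page = as.integer(page),
      offset = as.integer(offset),
      resolved = !is.na(target_row)
    )
  }
  if (length(out) == 0) {
    return(tibble(row = integer(0), link = character(0),
                  target_view = character(0), page = integer(0),
                  offset = integer(0), resolved = logical(0)))
  }
  bind_rows(out)
}

#' Split a detail table into per-key-value subtables
#'
#' One child table per distinct key value of the parent, containing exactly
#' the detail rows carrying that value in original order. Child view ids are
#' deterministic: `<view id>__<slug of the key value>` (percent-encoding
#' everything outside `[A-Za-z0-9_-]`); a collision of two distinct key
#' values after encoding is a hard error.
#'
#' @param parent Parent (overview) table.
#' @param key_column Column of `parent` holding the key values.
#' @param detail Detail table whose rows are partitioned by `key_column`.
#' @param view_id View id used to derive child view ids.
#' @return A tibble with columns `key`, `child_view` and a list-column
#'   `table` holding each child tibble.
#' @export
split_subtables <- function(parent, key_column, detail, view_id = "detail") {
  parent <- as_report_table(parent, "parent")
  detail <- as_report_table(detail, "detail")
  if (!key_column %in% names(parent)) {
    abort(glue("key column '{key_column}' is absent from the parent table"),
          class = "tabreport_link_error")
  }
  if (!key_column %in% names(detail)) {
    abort(glue("key column '{key_column}' is absent from the detail table"),
          class = "tabreport_link_error")
  }
  keys <- unique(canonical_text(parent[[key_column]]))
  keys <- keys[keys != ""]
  slugs <- slugify(keys)
  if (anyDuplicated(slugs)) {
    dup <- slugs[duplicated(slugs)][1]
    abort(glue("child view id collision after encoding: '{dup}'"),
          class = "tabreport_link_error")
  }
  detail_keys <- canonical_text(detail[[key_column]])
  children <- lapply(keys, function(k) detail[detail_keys == k, , drop = FALSE])
  tibble(
    key = keys,
    child_view = sprintf("%s__%s", view_id, slugs),
    table = children
  )
}
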