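# Reference implementation of the in-memory filter semantics. The embedded
# JavaScript runtime mirrors these rules exactly; this R counterpart defines
# the contract and lets the semantics be property-tested without a browser.
#
# A filter state maps column names to predicates:
#   list(kind = "any")
#   list(kind = "values", values = <character>)        discrete multi-select
#   list(kind = "keyword", keyword = <string>)         case-insensitive substring
#   list(kind = "interval", lo = <num|NULL>, hi = <num|NULL>)  numeric range
# Predicates combine conjunctively across columns; missing cells fail every
# predicate except "any".

#' Apply a filter state to a table
#'
#' Returns the subset of rows satisfying every column predicate (set
#' intersection across columns). Matching is on canonical cell text for
#' discrete and keyword predicates and on numeric values for intervals;
#' keyword matching is case-insensitive substring.
#'
#' @param table A data frame.
#' @param state Named list of predicates (see Details); columns without an
#'   entry are unconstrained.
#' @return The filtered tibble (original row order preserved).
#' @export
apply_filters <- function(table, state = list()) {
  table <- as_report_table(table)
  keep <- rep(TRUE, nrow(table))
  for (cn in names(state)) {
    pred <- state[[cn]]
    if (is.null(pred) || identical(pred$kind, "any")) next
    if (!cn %in% names(table)) {
      abort(glue("filter references unknown column '{cn}'"),
            class = "tabreport_type_error")
    }
    col <- table[[cn]]
    missing <- is.na(col) | (is.character(col) & !is.na(col) & col == "")
    ok <- switch(pred$kind,
      values = canonical_text(col) %in% pred$values,
      keyword = grepl(tolower(pred$keyword), tolower(canonical_text(col)),
                      fixed = TRUE),
      interval = {
        x <- suppressWarnings(as.numeric(col))
        pass <- !is.na(x)
        if (!is.null(pred$lo)) pass <- pass & x >= pred$lo
        if (!is.null(pred$hi)) pass <- pass & x <= pred$hi
        pass & !is.na(pass)
      },
      abort(glue("unknown predicate kind '{pred$kind}'"),
            class = "tabreport_type_error")
    )
    ok[is.na(ok)] <- FALSE
    ok[missing] <- FALSE
    keep <- keep & ok
  }
  table[keep, , drop = FALSE]
}

#' Filter widget kind for a column
#'
#' The filter mode shows, per column, a numeric interval brush for numeric
#' columns, a discrete multi-select when at most `cutoff` distinct values
#' occur, and a keyword search box otherwise.
#'
#' @param values The column's cells.
#' @param cutoff Multi-select cardinality cutoff.
#' @return `"interval"`, `"values"`, or `"keyword"`.
#' @export
filter_widget_kind <- function(values, cutoff = categorical_cutoff()) {
  if (is.numeric(values)) return("interval")
  texts <- canonical_text(values)
  texts <- texts[texts != ""]
  if (length(unique(texts)) <= cutoff) "values" else "keyword"
}
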