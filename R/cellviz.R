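# Per-cell and per-column visual computations: heatmap colors, tick/bar
# geometry, pill splitting, ellipsis truncation, linkout URLs, scientific
# notation, histograms. Colors interpolate in plain RGB with half-up
# rounding so results are exactly reproducible.

#' Heatmap color for a cell
#'
#' Linear scales position their color anchors evenly over `[min, max]` and
#' interpolate each RGB channel linearly between the two adjacent anchors,
#' rounding channels half-up; values outside the domain are clamped to the
#' endpoints when `clamp` is set. Categorical scales look the value up
#' exactly; a value absent from the mapping falls back to neutral white with
#' a warning.
#'
#' @param value The cell value (numeric for linear scales).
#' @param scale A heatmap scale: list with `kind` (`"linear"` or
#'   `"categorical"`), `domain`, `colors`, `clamp`.
#' @return A 7-character `#rrggbb` hex color.
#' @export
heatmap_color <- function(value, scale) {
  if (scale$kind == "categorical") {
    key <- canonical_text(value)
    color <- scale$colors[[key]]
    if (is.null(color)) {
      warn(glue("value '{key}' is not in the categorical scale; ",
                "using neutral #ffffff"),
           class = "tabreport_scale_warning")
      return("#ffffff")
    }
    return(tolower(color))
  }
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    return("#ffffff")
  }
  lo <- scale$domain[1]
  hi <- scale$domain[2]
  stopifnot(lo < hi)
  x <- (value - lo) / (hi - lo)
  if (isTRUE(scale$clamp %||% TRUE)) x <- min(1, max(0, x))
  anchors <- lapply(scale$colors, parse_hex_color)
  k <- length(anchors)
  pos <- x * (k - 1)
  i <- min(k - 1, max(1, floor(pos) + 1))
  frac <- pos - (i - 1)
  a <- anchors[[i]]
  b <- anchors[[min(k, i + 1)]]
  rgb <- round_half_up(a + frac * (b - a))
  format_hex_color(pmin(255, pmax(0, rgb)))
}

#' Position of a value within a tick-plot domain
#'
#' `(value - min) / (max - min)`, clamped into `[0, 1]`.
#'
#' @param value Numeric cell value.
#' @param domain Numeric `[min, max]` with `min < max`.
#' @return A fraction in `[0, 1]`, or `NA` for a non-numeric/missing cell
#'   (rendered as plain text, with a warning).
#' @export
tick_fraction <- function(value, domain) {
  stopifnot(is.numeric(domain), length(domain) == 2, domain[1] < domain[2])
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    warn("non-numeric cell in a tick/bar column is rendered as plain text",
         class = "tabreport_render_warning")
    return(NA_real_)
  }
  min(1, max(0, (value - domain[1]) / (domain[2] - domain[1])))
}

#' Bar geometry for a cell
#'
#' The bar's filled fraction follows [tick_fraction()]; the fill color comes
#' from the bar's color scale when one is configured, otherwise the default
#' steel-blue fill.
#'
#' @param value Numeric cell value.
#' @param spec Bar renderer spec: list with `domain` and optional
#'   `color_scale`.
#' @param default_fill Fill used without a color scale.
#' @return A list with `fraction` and `fill`.
#' @export
bar_geometry <- function(value, spec, default_fill = "#4682b4") {
  fraction <- tick_fraction(value, spec$domain)
  fill <- if (!is.null(spec$color_scale)) {
    heatmap_color(value, spec$color_scale)
  } else {
    default_fill
  }
  list(fraction = fraction, fill = fill)
}

#' Split a delimited multi-value cell into counted pills
#'
#' Splits on the separator, trims surrounding whitespace, drops empty
#' tokens, and counts duplicates; pills are ordered by first occurrence.
#'
#' @param text The cell text.
#' @param separator Single-character delimiter.
#' @return A tibble with columns `value` and `count`.
#' @export
split_pills <- function(text, separator = ",") {
  stopifnot(nchar(separator) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(value = character(0), count = integer(0)))
  }
  tokens <- trimws(strsplit(text, separator, fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    return(tibble(value = character(0), count = integer(0)))
  }
  values <- unique(tokens)
  tibble(value = values,
         count = as.integer(tabulate(match(tokens, values))))
}

#' Truncate cell text with an ellipsis
#'
#' Text longer than `n` characters is cut to its first `n` characters plus
#' an ellipsis glyph; the full text is preserved for the hover tooltip.
#'
#' @param text The cell text.
#' @param n Character limit (>= 1).
#' @return A list with `shown`, `full`, and `truncated`.
#' @export
truncate_ellipsis <- function(text, n) {
  stopifnot(is_count(n))
  text <- as.character(text)
  if (is.na(text)) text <- ""
  if (nchar(text, type = "chars") <= n) {
    return(list(shown = text, full = text, truncated = FALSE))
  }
  list(shown = paste0(substr(text, 1, n), "…"), full = text,
       truncated = TRUE)
}

linkout_placeholders <- function(template) {
  m <- gregexpr("\\{([^{}]+)\\}", template)
  tokens <- unlist(regmatches(template, m))
  unique(gsub("^\\{|\\}$", "", tokens))
}

#' Format a linkout URL from a template and a row
#'
#' `{value}` is replaced by the cell's value; `{column-name}` by the row's
#' value in that column. Substituted values are percent-encoded canonical
#' text.
#'
#' @param url_template URL template with `{...}` placeholders.
#' @param row Named list or one-row data frame: the source row.
#' @param value The cell value (`{value}`).
#' @return The formatted URL.
#' @export
format_linkout <- function(url_template, row, value) {
  if (is.data.frame(row)) row <- as.list(row)
  refs <- linkout_placeholders(url_template)
  url <- url_template
  for (ref in refs) {
    replacement <- if (ref == "value") {
      value
    } else if (ref %in% names(row)) {
      row[[ref]]
    } else {
      abort(glue("linkout template references unknown column '{ref}'"),
            class = "tabreport_link_error")
    }
    url <- gsub(paste0("{", ref, "}"),
                percent_encode(canonical_text(replacement)),
                url, fixed = TRUE)
  }
  url
}

#' Scientific notation for display
#'
#' Renders the mantissa with 3 significant digits and a signed power of ten
#' (`"3.20e-5"` style). Under `format = "auto"`, only nonzero values with
#' magnitude below 1e-3 or at least 1e6 are converted; everything else is
#' printed in plain canonical form. Zero prints as `"0"`.
#'
#' @param x A number.
#' @param format `"scientific"`, `"auto"`, or `"plain"`.
#' @return Display text.
#' @export
sci_notation <- function(x, format = "scientific") {
  stopifnot(is.numeric(x), length(x) == 1)
  if (is.na(x)) return("")
  if (x == 0) return("0")
  convert <- switch(format,
    scientific = TRUE,
    plain = FALSE,
    auto = abs(x) < 1e-3 || abs(x) >= 1e6,
    abort(glue("unknown numeric format '{format}'"),
          class = "tabreport_config_error")
  )
  if (!convert) {
    if (format == "plain") {
      return(format(x, scientific = FALSE, trim = TRUE, digits = 15))
    }
    return(canonical_text(x))
  }
  e <- floor(log10(abs(x)))
  m <- x / 10^e
  # Guard against mantissa rounding up to 10 at 3 significant digits.
  if (abs(round(m, 2)) >= 10) {
    m <- m / 10
    e <- e + 1
  }
  sprintf("%.2fe%s%d", m, if (e < 0) "-" else "+", abs(e))
}

#' Per-column histogram
#'
#' Numeric columns get up to 10 equal-width bins over the observed range
#' (one bin when the column is constant), right-open except for the last
#' bin. Nominal columns get value counts in descending order (ties by first
#' occurrence), truncated to the top 15.
#'
#' @param values The column's cells.
#' @param max_nominal Number of nominal values kept.
#' @return A `report_histogram` object: tibble with either `lo`, `hi`,
#'   `count` (numeric) or `value`, `count` (nominal), plus attributes
#'   `kind` and `n` (non-missing count).
#' @export
column_histogram <- function(values, max_nominal = 15L) {
  if (is.numeric(values) || is.logical(values)) {
    x <- as.numeric(values)
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      out <- tibble(lo = numeric(0), hi = numeric(0), count = integer(0))
      return(structure(out, kind = "numeric", n = 0L,
                       class = c("report_histogram", class(out))))
    }
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) {
      out <- tibble(lo = lo, hi = hi, count = length(x))
    } else {
      breaks <- seq(lo, hi, length.out = 11)
      bin <- pmin(10L, findInterval(x, breaks, rightmost.closed = FALSE))
      out <- tibble(lo = breaks[1:10], hi = breaks[2:11],
                    count = as.integer(tabulate(bin, nbins = 10)))
    }
    return(structure(out, kind = "numeric", n = length(x),
                     class = c("report_histogram", class(out))))
  }
  keys <- canonical_text(values)
  keys <- keys[keys != ""]
  values_order <- unique(keys)
  counts <- tabulate(match(keys, values_order), nbins = length(values_order))
  ord <- order(-counts, seq_along(values_order))
  out <- tibble(value = values_order[ord], count = as.integer(counts[ord]))
  out <- utils::head(out, max_nominal)
  structure(out, kind = "nominal", n = length(keys),
            class = c("report_histogram", class(out)))
}

#' @export
print.report_histogram <- function(x, ...) {
  cat(glue("<report_histogram> {attr(x, 'kind')}, ",
           "n = {attr(x, 'n')}\n"))
  NextMethod()
}
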