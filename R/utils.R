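# Shared helpers: canonical cell text, escaping, encoding, colors.

#' Canonical text form of cells
#'
#' One shared canonicalization used everywhere a cell value is compared or
#' keyed: foreign/primary key matching, search-index keys, linkout and share
#' payloads. Missing cells canonicalize to the empty string; logicals to
#' `"true"`/`"false"`; integral numbers print without an exponent so that the
#' number `1` and the text `"1"` coincide regardless of the input file format.
#'
#' @param x A vector of cells (character, numeric, integer, or logical).
#' @return A character vector of the same length.
#' @export
canonical_text <- function(x) {
  if (is.character(x)) {
    out <- x
  } else if (is.logical(x)) {
    out <- ifelse(x, "true", "false")
  } else if (is.integer(x)) {
    out <- as.character(x)
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      if (is.finite(v) && v == trunc(v) && abs(v) < 1e15) {
        sprintf("%.0f", v)
      } else {
        as.character(v)
      }
    }, character(1))
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&#39;", x, fixed = TRUE)
}

# Percent-encode everything outside the unreserved set (RFC 3986).
percent_encode <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) s <- ""
    bytes <- charToRaw(enc2utf8(s))
    chars <- rawToChar(as.raw(bytes), multiple = TRUE)
    ok <- grepl("^[A-Za-z0-9._~-]$", chars)
    chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# File-name slug: percent-encode everything outside [A-Za-z0-9_-].
slugify <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) s <- ""
    bytes <- charToRaw(enc2utf8(s))
    chars <- rawToChar(as.raw(bytes), multiple = TRUE)
    ok <- grepl("^[A-Za-z0-9_-]$", chars)
    chars[!ok] <- sprintf("%%%02X", as.integer(bytes[!ok]))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

parse_hex_color <- function(hex) {
  if (!grepl("^#[0-9a-fA-F]{6}$", hex)) {
    abort(glue("invalid hex color '{hex}' (expected #rrggbb)"),
          class = "tabreport_config_error")
  }
  as.integer(c(
    strtoi(substr(hex, 2, 3), 16L),
    strtoi(substr(hex, 4, 5), 16L),
    strtoi(substr(hex, 6, 7), 16L)
  ))
}

format_hex_color <- function(rgb) {
  sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])
}

# Round half up (the colour-interpolation rounding rule; R's round() rounds
# half to even, which is not what we document).
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == trunc(x) && x >= 1
}

# Validate that a tibble is usable as a report table: unique column names,
# supported column types. Factors are converted to character.
as_report_table <- function(df, name = "table") {
  if (!is.data.frame(df)) {
    abort(glue("'{name}' must be a data frame"), class = "tabreport_type_error")
  }
  df <- as_tibble(df)
  if (anyDuplicated(names(df))) {
    abort(glue("'{name}' has duplicated column names"),
          class = "tabreport_type_error")
  }
  df <- dplyr::mutate(df, across(dplyr::where(is.factor), as.character))
  bad <- names(df)[!vapply(df, function(col) {
    is.character(col) || is.numeric(col) || is.logical(col)
  }, logical(1))]
  if (length(bad) > 0) {
    abort(glue("'{name}': unsupported column type in {paste(bad, collapse = ', ')}"),
          class = "tabreport_type_error")
  }
  df
}
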