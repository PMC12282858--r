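# Memoized table packing (string dictionary + coded rows) and LZ-string
# compression of the serialized form. The packed wire format is this
# package's own deterministic dialect: a JSON document
#   {"v":1, "name":..., "h":[columns], "t":[column type codes],
#    "d":[dictionary strings], "r":[[row codes], ...]}
# where text cells are 0-based indices into "d" (first-occurrence order,
# scanning rows top-to-bottom and, within a row, left-to-right), numbers and
# booleans are stored as themselves, and missing cells are null. Column type
# codes: "s" text, "i" integer, "f" float, "b" boolean.

#' Pack a table into its memoized dictionary-encoded form
#'
#' Stores column names once, collects every distinct text cell into a
#' dictionary ordered by first occurrence (scanning rows top-to-bottom,
#' left-to-right), and replaces text cells by 0-based dictionary indices.
#' Numbers, booleans and missing cells are kept as themselves. Packing is
#' deterministic: identical input yields an identical packed object.
#'
#' @param table A data frame (the table to pack).
#' @param name Optional table name stored in the packed form.
#' @return A `packed_table` object.
#' @seealso [unpack_table()] for the exact inverse.
#' @export
pack_table <- function(table, name = "table") {
  table <- as_report_table(table, name)
  is_text <- vapply(table, is.character, logical(1))
  type_code <- vapply(table, function(col) {
    if (is.character(col)) "s"
    else if (is.logical(col)) "b"
    else if (is.integer(col)) "i"
    else "f"
  }, character(1))

  # First-occurrence dictionary in row-major order over the text columns.
  dict <- character(0)
  if (any(is_text) && nrow(table) > 0) {
    text_mat <- vapply(table[is_text], identity,
                       character(nrow(table)), USE.NAMES = FALSE)
    if (is.null(dim(text_mat))) text_mat <- matrix(text_mat, nrow = 1)
    row_major <- as.vector(t(text_mat))
    dict <- unique(row_major[!is.na(row_major)])
  }

  cols <- lapply(seq_along(table), function(j) {
    col <- table[[j]]
    if (is_text[j]) match(col, dict) - 1L else col
  })

  structure(
    list(name = name, header = names(table), types = unname(type_code),
         dict = dict, cols = cols, n_rows = nrow(table)),
    class = "packed_table"
  )
}

#' Unpack a memoized table
#'
#' Exact inverse of [pack_table()]: rebuilds the original tibble from the
#' dictionary and the coded rows.
#'
#' @param packed A `packed_table` object.
#' @return A tibble equal to the originally packed table.
#' @export
unpack_table <- function(packed) {
  stopifnot(inherits(packed, "packed_table"))
  n_dict <- length(packed$dict)
  cols <- lapply(seq_along(packed$header), function(j) {
    col <- packed$cols[[j]]
    if (packed$types[j] == "s") {
      codes <- col[!is.na(col)]
      if (length(codes) > 0 && (min(codes) < 0 || max(codes) >= n_dict)) {
        abort("packed table corrupt: dictionary index out of range",
              class = "tabreport_corruption_error")
      }
      out <- rep(NA_character_, length(col))
      out[!is.na(col)] <- packed$dict[codes + 1L]
      out
    } else {
      col
    }
  })
  names(cols) <- packed$header
  tibble::as_tibble(cols, .name_repair = "minimal")
}

#' @export
print.packed_table <- function(x, ...) {
  cat(glue("<packed_table> '{x$name}': {x$n_rows} rows, ",
           "{length(x$header)} columns, {length(x$dict)} dictionary entries\n"))
  invisible(x)
}

# Deterministic JSON serialization of a packed table (the payload body that
# gets LZ-compressed). Numbers use jsonlite's full-precision formatting.
packed_to_json <- function(packed) {
  coded <- stats::setNames(as.data.frame(packed$cols, optional = TRUE),
                           packed$header)
  doc <- list(
    v = 1L,
    name = packed$name,
    h = packed$header,
    t = packed$types,
    d = packed$dict,
    r = coded
  )
  as.character(jsonlite::toJSON(
    doc, dataframe = "values", na = "null", digits = NA,
    auto_unbox = TRUE, null = "null"
  ))
}

json_to_packed <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  header <- as.character(unlist(doc$h %||% character(0)))
  types <- as.character(unlist(doc$t %||% character(0)))
  dict <- as.character(unlist(doc$d %||% character(0)))
  rows <- doc$r %||% list()
  cols <- lapply(seq_along(header), function(j) {
    cells <- lapply(rows, function(row) row[[j]])
    cells <- lapply(cells, function(v) if (is.null(v)) NA else v)
    switch(types[j],
      s = as.integer(unlist(cells)),
      i = as.integer(unlist(cells)),
      f = as.numeric(unlist(cells)),
      b = as.logical(unlist(cells)),
      abort("packed payload corrupt: unknown column type",
            class = "tabreport_corruption_error")
    )
  })
  structure(
    list(name = doc$name %||% "table", header = header, types = types,
         dict = dict, cols = cols, n_rows = length(rows)),
    class = "packed_table"
  )
}

# ---- LZ-string --------------------------------------------------------------

#' LZ-string compression producing JavaScript-safe strings
#'
#' Compresses text with the LZ-string algorithm (an LZW variant with literal
#' escape codes and growing code width) into a string that can be embedded in
#' a JavaScript source file. Two output alphabets are supported:
#' `"utf16_safe"` packs 15 bits per character into printable UTF-16 code
#' units (used for data payloads embedded via script tags) and
#' `"uri_component"` packs 6 bits per character over a 65-character URL-safe
#' alphabet (used for share URLs).
#'
#' @param text A single string (any Unicode text).
#' @param alphabet `"utf16_safe"` or `"uri_component"`.
#' @return A `compressed_blob` object with fields `payload` and `alphabet`.
#' @export
lz_compress <- function(text, alphabet = c("utf16_safe", "uri_component")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  text <- enc2utf8(text)
  payload <- if (alphabet == "utf16_safe") {
    .lz_compress_utf16_cpp(text)
  } else {
    .lz_compress_uri_cpp(text)
  }
  structure(list(payload = payload, alphabet = alphabet),
            class = "compressed_blob")
}

#' Decompress an LZ-string blob
#'
#' Exact inverse of [lz_compress()]. A payload that cannot be decoded raises
#' a corruption error rather than returning truncated text.
#'
#' @param blob A `compressed_blob`, or a single string (then `alphabet` must
#'   be given).
#' @param alphabet Alphabet of `blob` when it is a bare string.
#' @return The original text.
#' @export
lz_decompress <- function(blob, alphabet = NULL) {
  if (inherits(blob, "compressed_blob")) {
    payload <- blob$payload
    alphabet <- blob$alphabet
  } else {
    stopifnot(is.character(blob), length(blob) == 1)
    payload <- blob
    alphabet <- match.arg(alphabet, c("utf16_safe", "uri_component"))
  }
  payload <- enc2utf8(payload)
  out <- if (alphabet == "utf16_safe") {
    .lz_decompress_utf16_cpp(payload)
  } else {
    .lz_decompress_uri_cpp(payload)
  }
  if (is.null(out)) {
    abort("compressed payload is corrupt and cannot be decoded",
          class = "tabreport_corruption_error")
  }
  out
}

#' @export
print.compressed_blob <- function(x, ...) {
  cat(glue("<compressed_blob> alphabet={x$alphabet}, ",
           "{nchar(x$payload, type = 'chars')} characters\n"))
  invisible(x)
}

# Compress a table payload end to end: pack, serialize, compress.
compress_table_payload <- function(table, name = "table") {
  lz_compress(packed_to_json(pack_table(table, name)), "utf16_safe")
}

# ---- size reporting ---------------------------------------------------------

#' Raw vs packed-and-compressed size summary
#'
#' Measures the byte footprint of a table as plain CSV, as the packed JSON
#' document, and as the LZ-compressed payload — for the whole table and,
#' optionally, summed over pages of given sizes (each page compressed
#' separately, as in a partitioned report).
#'
#' @param table A data frame.
#' @param page_sizes Optional integer vector of page sizes to additionally
#'   measure (each page packed and compressed on its own).
#' @return A tibble with columns `serialization`, `bytes`, and `ratio`
#'   (raw CSV bytes divided by the serialization's bytes).
#' @export
compression_report <- function(table, page_sizes = NULL) {
  table <- as_report_table(table)
  raw_csv <- nchar(readr::format_csv(table), type = "bytes")
  packed_json <- packed_to_json(pack_table(table))
  packed_bytes <- nchar(packed_json, type = "bytes")
  compressed_bytes <- nchar(lz_compress(packed_json)$payload, type = "bytes")

  rows <- tibble(
    serialization = c("raw_csv", "packed_json", "compressed"),
    bytes = c(raw_csv, packed_bytes, compressed_bytes)
  )
  for (ps in page_sizes) {
    pages <- paginate(table, ps)
    total <- sum(vapply(pages, function(p) {
      nchar(compress_table_payload(p$rows)$payload, type = "bytes")
    }, numeric(1)))
    rows <- bind_rows(rows, tibble(
      serialization = sprintf("compressed_pages_%d", as.integer(ps)),
      bytes = total
    ))
  }
  out <- dplyr::mutate(rows, ratio = raw_csv / bytes)
  class(out) <- c("compression_report", class(out))
  out
}
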