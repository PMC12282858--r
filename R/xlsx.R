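# Minimal XLSX (OOXML spreadsheet) writer. Text cells are written as inline
# strings with an explicit text type so identifiers like gene symbols can
# never be reinterpreted (e.g. as dates) on re-import; numeric cells are
# written as numbers. The zip container is produced in-package: entries are
# deflated via R's zlib stream (header and Adler32 trailer stripped) with a
# CRC-32 computed natively, and all timestamps are fixed so output is
# byte-identical across runs.

u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}
u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

deflate_raw <- function(data) {
  z <- memCompress(data, type = "gzip")  # zlib stream (RFC 1950)
  z[3:(length(z) - 4)]
}

# entries: named list of raw vectors (name = path inside the archive).
write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  offset <- 0
  dos_time <- u16(0L)           # 00:00:00
  dos_date <- u16(0x0021L)      # 1980-01-01
  for (name in names(entries)) {
    data <- entries[[name]]
    crc <- .crc32_cpp(data)
    comp <- deflate_raw(data)
    method <- 8L
    if (length(comp) >= length(data)) {
      comp <- data
      method <- 0L
    }
    name_raw <- charToRaw(name)
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      u16(20), u16(0), u16(method), dos_time, dos_date,
      u32(crc), u32(length(comp)), u32(length(data)),
      u16(length(name_raw)), u16(0)
    )
    writeBin(c(header, name_raw, comp), con)
    centrals[[length(centrals) + 1]] <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      u16(20), u16(20), u16(0), u16(method), dos_time, dos_date,
      u32(crc), u32(length(comp)), u32(length(data)),
      u16(length(name_raw)), u16(0), u16(0), u16(0), u16(0),
      u32(0), u32(offset), name_raw
    )
    offset <- offset + length(header) + length(name_raw) + length(comp)
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  writeBin(c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    u16(0), u16(0), u16(length(entries)), u16(length(entries)),
    u32(length(cd)), u32(offset), u16(0)
  ), con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  # Control characters are not representable in XML 1.0.
  gsub("[\x01-\x08\x0b\x0c\x0e-\x1f]", "", x)
}

column_letter <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

sheet_xml <- function(table) {
  n <- nrow(table)
  k <- ncol(table)
  letters_k <- column_letter(seq_len(k))
  rows <- character(n + 1)
  header_cells <- sprintf(
    '<c r="%s1" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
    letters_k, xml_escape(names(table))
  )
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header_cells, collapse = ""))

  cell_chunks <- lapply(seq_len(k), function(j) {
    col <- table[[j]]
    ref <- sprintf("%s%d", letters_k[j], seq_len(n) + 1L)
    if (is.numeric(col)) {
      out <- sprintf('<c r="%s"><v>%s</v></c>', ref, canonical_number(col))
    } else if (is.logical(col)) {
      out <- sprintf('<c r="%s" t="b"><v>%d</v></c>', ref, as.integer(col))
    } else {
      out <- sprintf(
        '<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        ref, xml_escape(as.character(col)))
    }
    out[is.na(col)] <- ""
    out
  })
  if (n > 0) {
    mat <- do.call(cbind, cell_chunks)
    body <- apply(mat, 1, paste, collapse = "")
    rows[-1] <- sprintf('<row r="%d">%s</row>', seq_len(n) + 1L, body)
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>'
  )
}

# Full-precision number formatting for XML cell values.
canonical_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.finite(v) && v == trunc(v) && abs(v) < 1e15) sprintf("%.0f", v)
    else as.character(v)
  }, character(1))
}

sanitize_sheet_names <- function(ids) {
  names_out <- gsub("[\\[\\]:*?/\\\\]", "_", ids)
  names_out <- substr(names_out, 1, 28)
  seen <- character(0)
  for (i in seq_along(names_out)) {
    base <- names_out[i]
    cand <- base
    suffix <- 1
    while (cand %in% seen) {
      suffix <- suffix + 1
      cand <- sprintf("%s_%d", base, suffix)
    }
    names_out[i] <- cand
    seen <- c(seen, cand)
  }
  names_out
}

#' Export tables to an XLSX workbook
#'
#' One sheet per table. Numeric cells are written as numbers; every text
#' cell is written as an explicit inline string, so identifiers (such as the
#' gene symbol `SEPT2`) survive a round trip through spreadsheet software
#' without being auto-converted to dates. Sheet-name collisions are resolved
#' by a numeric suffix. Output is byte-deterministic.
#'
#' @param tables A named list of data frames (names become sheet names), or
#'   a single data frame.
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
export_xlsx <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(table = tables)
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- sprintf("sheet_%d", seq_along(tables))
  }
  tables <- lapply(tables, as_report_table)
  sheet_names <- sanitize_sheet_names(names(tables))
  n <- length(tables)

  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      seq_len(n)), collapse = ""),
    '</Types>'
  )
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'
  )
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(sheet_names), seq_len(n), seq_len(n)),
          collapse = ""),
    '</sheets></workbook>'
  )
  workbook_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
      seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>'
  )

  entries <- list()
  entries[["[Content_Types].xml"]] <- charToRaw(content_types)
  entries[["_rels/.rels"]] <- charToRaw(rels)
  entries[["xl/workbook.xml"]] <- charToRaw(workbook)
  entries[["xl/_rels/workbook.xml.rels"]] <- charToRaw(workbook_rels)
  for (i in seq_len(n)) {
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(enc2utf8(sheet_xml(tables[[i]])))
  }
  write_zip(entries, path)
  invisible(path)
}
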