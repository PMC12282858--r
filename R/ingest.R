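# Reading tabular inputs (CSV, TSV, JSON, Parquet) into tibbles, inferring
# column types from raw text, and auto-generating a starter configuration.

#' Infer the type of a column from raw text cells
#'
#' Classification precedence: all non-missing values parse as integers ->
#' `integer`; else all parse as decimal or scientific numbers -> `float`;
#' else all are (case-insensitively) `"true"`/`"false"` -> `boolean_like`;
#' else `nominal`. The empty string is the only missing token — tokens such
#' as `"NA"` or `"NaN"` stay nominal text, so identifiers are never silently
#' coerced.
#'
#' @param values Character vector of raw cells (`NA` and `""` both count as
#'   missing).
#' @return A `column_type` object: list with `kind`, `has_missing`,
#'   `distinct_count`, and (for numeric kinds) `observed_min`/`observed_max`.
#' @export
infer_column_type <- function(values) {
  values <- as.character(values)
  missing <- is.na(values) | values == ""
  present <- values[!missing]
  distinct_count <- length(unique(present))

  kind <- "nominal"
  obs_min <- NA_real_
  obs_max <- NA_real_
  if (length(present) > 0) {
    if (all(grepl("^[+-]?[0-9]+$", present))) {
      kind <- "integer"
    } else {
      nums <- suppressWarnings(as.numeric(present))
      if (!anyNA(nums)) {
        kind <- "float"
      } else if (all(tolower(present) %in% c("true", "false"))) {
        kind <- "boolean_like"
      }
    }
    if (kind %in% c("integer", "float")) {
      nums <- as.numeric(present)
      obs_min <- min(nums)
      obs_max <- max(nums)
    }
  }
  structure(
    list(kind = kind, has_missing = any(missing),
         distinct_count = distinct_count,
         observed_min = obs_min, observed_max = obs_max),
    class = "column_type"
  )
}

#' @export
print.column_type <- function(x, ...) {
  cat(glue("<column_type> {x$kind}, {x$distinct_count} distinct",
           "{if (x$has_missing) ', has missing' else ''}\n"))
  invisible(x)
}

# Convert a raw character column to its inferred R type.
typed_column <- function(values, ctype = infer_column_type(values)) {
  values <- as.character(values)
  values[!is.na(values) & values == ""] <- NA_character_
  switch(ctype$kind,
    integer = {
      nums <- as.numeric(values)
      if (all(is.na(nums) | abs(nums) <= .Machine$integer.max)) {
        as.integer(nums)
      } else {
        nums
      }
    },
    float = as.numeric(values),
    boolean_like = tolower(values) == "true",
    values
  )
}

#' Read a tabular input file into a tibble
#'
#' Supports CSV, TSV (any single-character separator), Parquet (flat schemas)
#' and JSON (a top-level array of flat objects; the union of keys, in first
#' appearance order, becomes the columns and absent keys become missing
#' cells). For delimited text the cells are typed by the inference rules of
#' [infer_column_type()]; Parquet and JSON carry their own types.
#'
#' @param spec A dataset specification (as produced by [load_config()]), or a
#'   bare file path (format then inferred from the extension).
#' @param separator Field separator for csv/tsv when `spec` is a bare path.
#' @param has_header Whether the first row holds column names (csv/tsv).
#' @return A tibble.
#' @export
read_table <- function(spec, separator = NULL, has_header = TRUE) {
  if (is.character(spec)) {
    spec <- dataset_spec_from_path(spec, separator = separator,
                                   has_header = has_header)
  }
  path <- spec$path
  if (!file.exists(path)) {
    abort(glue("input file '{path}' does not exist"),
          class = "tabreport_io_error")
  }
  switch(spec$format,
    csv = ,
    tsv = read_delim_table(path, spec$separator, spec$has_header),
    parquet = read_parquet_table(path),
    json = read_json_table(path),
    abort(glue("unsupported format '{spec$format}'"),
          class = "tabreport_config_error")
  )
}

dataset_spec_from_path <- function(path, separator = NULL, has_header = TRUE) {
  ext <- tolower(tools::file_ext(path))
  format <- switch(ext,
    csv = "csv", tsv = "tsv", tab = "tsv", txt = "tsv",
    parquet = "parquet", json = "json",
    abort(glue("cannot infer format from extension '.{ext}' of '{path}'"),
          class = "tabreport_config_error")
  )
  sep <- separator %||% if (format == "csv") "," else "\t"
  list(id = tools::file_path_sans_ext(basename(path)), path = path,
       format = format, separator = sep, has_header = isTRUE(has_header),
       links = list())
}

read_delim_table <- function(path, separator, has_header) {
  raw <- suppressWarnings(readr::read_delim(
    path, delim = separator, col_names = has_header,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(0), quote = "\"", trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE, name_repair = "minimal"
  ))  # malformed records surface as a tabreport_io_error below
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    bad_row <- probs$row[1]
    abort(glue("malformed record in '{path}' at row {bad_row}: ",
               "{probs$expected[1]}, got {probs$actual[1]}"),
          class = "tabreport_io_error")
  }
  if (!has_header) {
    names(raw) <- sprintf("column_%d", seq_along(raw))
  }
  if (anyDuplicated(names(raw))) {
    abort(glue("duplicated column names in '{path}'"),
          class = "tabreport_io_error")
  }
  dplyr::mutate(raw, across(dplyr::everything(), typed_column))
}

read_parquet_table <- function(path) {
  df <- arrow::read_parquet(path)
  bad <- names(df)[vapply(df, function(col) is.list(col) || is.data.frame(col),
                          logical(1))]
  if (length(bad) > 0) {
    abort(glue("nested columns in parquet file '{path}' are unsupported: ",
               "{paste(bad, collapse = ', ')}"),
          class = "tabreport_io_error")
  }
  df <- as_tibble(df)
  dplyr::mutate(df, across(dplyr::where(~ inherits(.x, "integer64")), as.numeric),
                across(dplyr::where(is.factor), as.character))
}

read_json_table <- function(path) {
  records <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(glue("cannot parse JSON file '{path}': ",
                                   "{conditionMessage(e)}"),
                              class = "tabreport_io_error")
  )
  if (!is.list(records) || (length(records) > 0 && !is.null(names(records)))) {
    abort(glue("JSON input '{path}' must be a top-level array of objects"),
          class = "tabreport_io_error")
  }
  columns <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!is.list(rec) || is.null(names(rec)) || any(names(rec) == "")) {
      abort(glue("JSON input '{path}': element {i} is not an object"),
            class = "tabreport_io_error")
    }
    nested <- vapply(rec, function(v) is.list(v) || length(v) > 1, logical(1))
    if (any(nested)) {
      abort(glue("JSON input '{path}': nested value in key ",
                 "'{names(rec)[nested][1]}' of element {i} is unsupported"),
            class = "tabreport_io_error")
    }
    columns <- union(columns, names(rec))
  }
  cols <- lapply(columns, function(cn) {
    cells <- lapply(records, function(rec) {
      v <- rec[[cn]]
      if (is.null(v)) NA else v
    })
    kinds <- vapply(cells, function(v) {
      if (length(v) == 1 && is.na(v)) "missing"
      else if (is.character(v)) "chr"
      else if (is.logical(v)) "lgl"
      else if (is.numeric(v)) "num"
      else "other"
    }, character(1))
    present <- setdiff(unique(kinds), "missing")
    if (length(present) == 1 && present == "num") {
      vals <- vapply(cells, function(v) if (length(v) == 1 && is.na(v)) NA_real_ else as.numeric(v), numeric(1))
      if (all(is.na(vals) | (is.finite(vals) & vals == trunc(vals) &
                               abs(vals) <= .Machine$integer.max))) {
        as.integer(vals)
      } else {
        vals
      }
    } else if (length(present) == 1 && present == "lgl") {
      vapply(cells, function(v) if (length(v) == 1 && is.na(v)) NA else as.logical(v), logical(1))
    } else {
      vapply(cells, function(v) {
        if (length(v) == 1 && is.na(v)) NA_character_ else canonical_text(v)
      }, character(1))
    }
  })
  names(cols) <- columns
  tibble::as_tibble(cols, .name_repair = "minimal")
}

# ---- configuration suggestion ----------------------------------------------

#' Suggest a report configuration for a set of tables
#'
#' Builds a starter configuration with one dataset and one table view per
#' input: numeric columns get a linear heatmap over their observed range,
#' nominal columns with at most `categorical_cutoff()` distinct values get a
#' categorical heatmap with palette-assigned colors, boolean-like columns get
#' the boolean display spell, and everything else stays plain. The output is
#' guaranteed to load and validate cleanly.
#'
#' @param tables A named list of data frames (names become dataset/view ids),
#'   or a single data frame.
#' @param paths Optional character vector of input file paths, one per table
#'   (defaults to `<name>.csv`).
#' @return The configuration as a single YAML string.
#' @export
suggest_config <- function(tables, paths = NULL) {
  if (is.data.frame(tables)) tables <- list(table = tables)
  if (length(tables) < 1) {
    abort("suggest_config needs at least one table", class = "tabreport_config_error")
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- sprintf("table_%d", seq_along(tables))
  }
  paths <- paths %||% sprintf("%s.csv", names(tables))
  stopifnot(length(paths) == length(tables))

  datasets <- list()
  views <- list()
  for (i in seq_along(tables)) {
    id <- names(tables)[i]
    tab <- as_report_table(tables[[i]], id)
    if (ncol(tab) == 0) {
      abort(glue("table '{id}' has no columns"), class = "tabreport_config_error")
    }
    fmt <- tolower(tools::file_ext(paths[i]))
    if (!fmt %in% c("csv", "tsv", "parquet", "json")) fmt <- "csv"
    ds <- list(path = paths[i], format = fmt)
    if (fmt %in% c("csv", "tsv")) {
      ds$separator <- if (fmt == "csv") "," else "\t"
    }
    datasets[[id]] <- ds
    columns <- lapply(names(tab), function(cn) {
      suggest_column(canonical_text(tab[[cn]]))
    })
    names(columns) <- names(tab)
    views[[id]] <- list(dataset = id, render_kind = "table", columns = columns)
  }

  config <- list(
    report_name = "Suggested report",
    datasets = datasets,
    views = views
  )
  yaml::as.yaml(config, indent.mapping.sequence = TRUE)
}

suggest_column <- function(raw_values) {
  ctype <- infer_column_type(raw_values)
  if (ctype$kind %in% c("integer", "float")) {
    if (!is.na(ctype$observed_min) && ctype$observed_min < ctype$observed_max) {
      return(list(renderer = list(
        kind = "heatmap",
        scale = list(kind = "linear",
                     domain = c(ctype$observed_min, ctype$observed_max),
                     colors = as.list(tabreport_linear_palette),
                     clamp = TRUE)
      )))
    }
    return(list(renderer = list(kind = "plain")))
  }
  if (ctype$kind == "boolean_like") {
    return(list(spell = list(identifier = "boolean",
                             with = list(true_value = "true",
                                         false_value = "false"))))
  }
  if (ctype$kind == "nominal" && ctype$distinct_count >= 1 &&
      ctype$distinct_count <= categorical_cutoff()) {
    vals <- unique(raw_values[!is.na(raw_values) & raw_values != ""])
    colors <- as.list(stats::setNames(
      tabreport_palette[seq_along(vals)], vals))
    return(list(renderer = list(
      kind = "heatmap",
      scale = list(kind = "categorical", domain = as.list(vals),
                   colors = colors)
    )))
  }
  list(renderer = list(kind = "plain"))
}
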