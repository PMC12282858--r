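# Declarative report configuration: YAML parsing, strict normalization
# (unknown keys are hard errors), spell application, and cross-table
# validation. The machine-readable schema ships at
# inst/schema/report-config.schema.json and is the single source of truth
# for the dialect.

RENDERER_KINDS <- c("plain", "tick", "bar", "heatmap", "pills",
                    "custom_script", "custom_plot")
DISPLAY_MODES <- c("normal", "detail", "available", "pinned", "hidden")
NUMERIC_FORMATS <- c("auto", "scientific", "plain")

config_error <- function(msg, path = NULL) {
  where <- if (!is.null(path)) glue(" (at {path})") else ""
  abort(glue("invalid configuration: {msg}{where}"),
        class = "tabreport_config_error")
}

check_keys <- function(x, allowed, path) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    config_error(glue("unknown key '{unknown[1]}'"), path)
  }
  invisible()
}

scalar_chr <- function(x, what, path, optional = FALSE) {
  if (is.null(x)) {
    if (optional) return(NULL)
    config_error(glue("missing required key '{what}'"), path)
  }
  if (!is.atomic(x) || length(x) != 1 || is.na(x)) {
    config_error(glue("'{what}' must be a single value"), path)
  }
  as.character(x)
}

scalar_flag <- function(x, what, path, default = FALSE) {
  if (is.null(x)) return(default)
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    config_error(glue("'{what}' must be true or false"), path)
  }
  x
}

scalar_int <- function(x, what, path, default = NULL, min = 1L) {
  if (is.null(x)) return(default)
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != trunc(x)) {
    config_error(glue("'{what}' must be an integer"), path)
  }
  if (x < min) {
    config_error(glue("'{what}' must be >= {min}"), path)
  }
  as.integer(x)
}

#' Load and normalize a report configuration
#'
#' Parses YAML text (or a file), applies defaults (`default_page_size` =
#' 20000 when absent), resolves spells into column settings (explicit column
#' settings win over spell-provided ones), and rejects unknown keys anywhere
#' in the document, naming the offending key path.
#'
#' @param yaml_text A single string of YAML, or the path of a YAML file.
#' @param spell_dirs Directories searched for spell files by identifier, in
#'   order; the package's built-in spells are always searched last.
#' @return A `report_config` object.
#' @export
load_config <- function(yaml_text, spell_dirs = character(0)) {
  if (length(yaml_text) == 1 && !grepl("\n", yaml_text) &&
      file.exists(yaml_text)) {
    yaml_text <- paste(readLines(yaml_text, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n")
  }
  stopifnot(is.character(yaml_text))
  yaml_text <- paste(yaml_text, collapse = "\n")
  doc <- tryCatch(
    yaml::yaml.load(yaml_text),
    error = function(e) {
      abort(glue("configuration is not valid YAML: {conditionMessage(e)}"),
            class = "tabreport_parse_error")
    }
  )
  if (!is.list(doc) || is.null(names(doc))) {
    config_error("top level must be a mapping")
  }
  check_keys(doc, c("report_name", "default_page_size", "share_base_url",
                    "datasets", "views"), "top level")

  config <- list(
    report_name = scalar_chr(doc$report_name, "report_name", "top level",
                             optional = TRUE) %||% "Report",
    default_page_size = scalar_int(doc$default_page_size, "default_page_size",
                                   "top level", default = default_page_size()),
    share_base_url = scalar_chr(doc$share_base_url, "share_base_url",
                                "top level", optional = TRUE),
    datasets = list(),
    views = list()
  )

  if (is.null(doc$datasets) || length(doc$datasets) == 0) {
    config_error("report has no datasets", "datasets")
  }
  if (is.null(names(doc$datasets)) || any(names(doc$datasets) == "")) {
    config_error("datasets must be a mapping of id to dataset", "datasets")
  }
  config$datasets <- lapply(seq_along(doc$datasets), function(i) {
    normalize_dataset(doc$datasets[[i]], names(doc$datasets)[i])
  })
  names(config$datasets) <- names(doc$datasets)

  if (is.null(doc$views) || length(doc$views) == 0) {
    config_error("report has no views", "views")
  }
  if (is.null(names(doc$views)) || any(names(doc$views) == "")) {
    config_error("views must be a mapping of id to view", "views")
  }
  config$views <- lapply(seq_along(doc$views), function(i) {
    normalize_view(doc$views[[i]], names(doc$views)[i], config, spell_dirs)
  })
  names(config$views) <- names(doc$views)

  # Every link's target view / detail dataset must exist.
  for (ds_id in names(config$datasets)) {
    for (link in config$datasets[[ds_id]]$links) {
      if (link$kind == "row_link" &&
          !link$target_view %in% names(config$views)) {
        config_error(
          glue("link '{link$name}' targets unknown view '{link$target_view}'"),
          glue("datasets.{ds_id}.links.{link$name}"))
      }
      if (link$kind == "subtable_link" &&
          !link$detail_dataset %in% names(config$datasets)) {
        config_error(
          glue("link '{link$name}' references unknown detail dataset ",
               "'{link$detail_dataset}'"),
          glue("datasets.{ds_id}.links.{link$name}"))
      }
    }
  }

  structure(config, class = "report_config")
}

normalize_dataset <- function(ds, id) {
  path <- glue("datasets.{id}")
  if (!is.list(ds)) config_error("dataset must be a mapping", path)
  check_keys(ds, c("path", "format", "separator", "has_header", "links"), path)
  file_path <- scalar_chr(ds$path, "path", path)
  if (!nzchar(file_path)) config_error("'path' must be nonempty", path)
  format <- scalar_chr(ds$format, "format", path, optional = TRUE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(file_path))
    format <- switch(ext, csv = "csv", tsv = "tsv", tab = "tsv",
                     parquet = "parquet", json = "json", "csv")
  }
  if (!format %in% c("csv", "tsv", "json", "parquet")) {
    config_error(glue("unknown format '{format}'"), path)
  }
  separator <- scalar_chr(ds$separator, "separator", path, optional = TRUE)
  if (format %in% c("csv", "tsv")) {
    separator <- separator %||% if (format == "csv") "," else "\t"
    if (nchar(separator) != 1) {
      config_error("'separator' must be a single character", path)
    }
  } else {
    separator <- NULL
  }
  links <- list()
  if (!is.null(ds$links)) {
    if (!is.list(ds$links) || is.null(names(ds$links))) {
      config_error("'links' must be a mapping of name to link", path)
    }
    links <- lapply(seq_along(ds$links), function(i) {
      normalize_link(ds$links[[i]], names(ds$links)[i], path)
    })
    names(links) <- names(ds$links)
  }
  list(id = id, path = file_path, format = format, separator = separator,
       has_header = scalar_flag(ds$has_header, "has_header", path,
                                default = TRUE),
       links = links)
}

normalize_link <- function(link, name, ds_path) {
  path <- glue("{ds_path}.links.{name}")
  if (!is.list(link)) config_error("link must be a mapping", path)
  check_keys(link, c("kind", "source_column", "target_view",
                     "target_key_column", "detail_dataset", "optional"), path)
  kind <- scalar_chr(link$kind, "kind", path)
  if (!kind %in% c("row_link", "subtable_link")) {
    config_error(glue("unknown link kind '{kind}'"), path)
  }
  source_column <- scalar_chr(link$source_column, "source_column", path)
  detail_dataset <- NULL
  if (kind == "row_link") {
    target_view <- scalar_chr(link$target_view, "target_view", path)
    target_key_column <- scalar_chr(link$target_key_column,
                                    "target_key_column", path)
    if (!is.null(link$detail_dataset)) {
      config_error("row_link must not set detail_dataset", path)
    }
  } else {
    if (!is.null(link$target_view) || !is.null(link$target_key_column)) {
      config_error("subtable_link must not set target_view/target_key_column",
                   path)
    }
    target_view <- NULL
    target_key_column <- NULL
    detail_dataset <- scalar_chr(link$detail_dataset, "detail_dataset", path)
  }
  list(name = name, kind = kind, source_column = source_column,
       target_view = target_view, target_key_column = target_key_column,
       detail_dataset = detail_dataset,
       optional = scalar_flag(link$optional, "optional", path))
}

normalize_view <- function(view, id, config, spell_dirs) {
  path <- glue("views.{id}")
  if (!is.list(view)) config_error("view must be a mapping", path)
  check_keys(view, c("dataset", "description", "page_size", "render_kind",
                     "columns", "plot_spec", "html_body", "show_line_numbers",
                     "extra_header_rows"), path)
  dataset <- scalar_chr(view$dataset, "dataset", path)
  if (!dataset %in% names(config$datasets)) {
    config_error(glue("view references unknown dataset '{dataset}'"), path)
  }
  render_kind <- scalar_chr(view$render_kind, "render_kind", path,
                            optional = TRUE) %||% "table"
  if (!render_kind %in% c("table", "plot", "html")) {
    config_error(glue("unknown render_kind '{render_kind}'"), path)
  }
  populated <- c(columns = !is.null(view$columns),
                 plot_spec = !is.null(view$plot_spec),
                 html_body = !is.null(view$html_body))
  required <- switch(render_kind, table = "columns", plot = "plot_spec",
                     html = "html_body")
  wrong <- names(populated)[populated & names(populated) != required]
  if (length(wrong) > 0) {
    config_error(glue("'{wrong[1]}' cannot be set on a {render_kind} view"),
                 path)
  }

  columns <- list()
  plot_spec <- NULL
  html_body <- NULL
  if (render_kind == "table") {
    if (!is.null(view$columns)) {
      if (!is.list(view$columns) || is.null(names(view$columns))) {
        config_error("'columns' must be a mapping of column name to settings",
                     path)
      }
      columns <- lapply(seq_along(view$columns), function(i) {
        normalize_column(view$columns[[i]], names(view$columns)[i], path,
                         spell_dirs)
      })
      names(columns) <- names(view$columns)
    }
  } else if (render_kind == "plot") {
    if (!is.list(view$plot_spec)) {
      config_error("'plot_spec' must be a mapping (a grammar-of-graphics document)",
                   path)
    }
    plot_spec <- view$plot_spec
  } else {
    html_body <- scalar_chr(view$html_body, "html_body", path)
  }

  list(id = id, dataset = dataset,
       description = scalar_chr(view$description, "description", path,
                                optional = TRUE),
       page_size = if (!is.null(view$page_size)) {
         if (!is.numeric(view$page_size) || length(view$page_size) != 1 ||
             is.na(view$page_size) || view$page_size != trunc(view$page_size)) {
           config_error("'page_size' must be an integer", path)
         }
         as.integer(view$page_size)
       },
       render_kind = render_kind, columns = columns, plot_spec = plot_spec,
       html_body = html_body,
       show_line_numbers = scalar_flag(view$show_line_numbers,
                                       "show_line_numbers", path),
       extra_header_rows = scalar_int(view$extra_header_rows,
                                      "extra_header_rows", path,
                                      default = 0L, min = 0L))
}

normalize_column <- function(col, name, view_path, spell_dirs,
                             allow_spell = TRUE) {
  path <- glue("{view_path}.columns.{name}")
  if (is.null(col)) col <- list()
  if (!is.list(col)) config_error("column settings must be a mapping", path)
  check_keys(col, c("label", "description", "display_mode", "renderer",
                    "ellipsis_limit", "linkouts", "numeric_format", "spell"),
             path)
  display_mode <- scalar_chr(col$display_mode, "display_mode", path,
                             optional = TRUE)
  if (!is.null(display_mode) && !display_mode %in% DISPLAY_MODES) {
    config_error(glue("unknown display_mode '{display_mode}'"), path)
  }
  numeric_format <- scalar_chr(col$numeric_format, "numeric_format", path,
                               optional = TRUE)
  if (!is.null(numeric_format) && !numeric_format %in% NUMERIC_FORMATS) {
    config_error(glue("unknown numeric_format '{numeric_format}'"), path)
  }
  ellipsis_limit <- scalar_int(col$ellipsis_limit, "ellipsis_limit", path)
  renderer <- if (!is.null(col$renderer)) {
    normalize_renderer(col$renderer, path)
  }
  linkouts <- list()
  if (!is.null(col$linkouts)) {
    if (!is.list(col$linkouts) || !is.null(names(col$linkouts))) {
      config_error("'linkouts' must be a sequence", path)
    }
    linkouts <- lapply(seq_along(col$linkouts), function(i) {
      lo <- col$linkouts[[i]]
      lo_path <- glue("{path}.linkouts[{i}]")
      check_keys(lo, c("name", "url_template"), lo_path)
      list(name = scalar_chr(lo$name, "name", lo_path),
           url_template = scalar_chr(lo$url_template, "url_template", lo_path))
    })
  }

  spec <- list(column = name,
               label = scalar_chr(col$label, "label", path, optional = TRUE),
               description = scalar_chr(col$description, "description", path,
                                        optional = TRUE),
               display_mode = display_mode, renderer = renderer,
               ellipsis_limit = ellipsis_limit, linkouts = linkouts,
               numeric_format = numeric_format)

  if (!is.null(col$spell)) {
    if (!allow_spell) {
      config_error("a spell body cannot itself invoke a spell", path)
    }
    sp_path <- glue("{path}.spell")
    check_keys(col$spell, c("identifier", "with"), sp_path)
    identifier <- scalar_chr(col$spell$identifier, "identifier", sp_path)
    with_params <- col$spell$with %||% list()
    spell <- load_spell(identifier, spell_dirs)
    fragment <- resolve_spell(spell, with_params, column = name)
    spec <- merge_column_spec(spec, fragment)
    spec$spell <- list(identifier = identifier, with = with_params)
  }

  # Built-in defaults fill whatever is still unset.
  spec$label <- spec$label %||% name
  spec$display_mode <- spec$display_mode %||% "normal"
  spec$numeric_format <- spec$numeric_format %||% "auto"
  spec$renderer <- spec$renderer %||% list(kind = "plain")
  spec
}

# Explicit settings win over the fragment's settings.
merge_column_spec <- function(explicit, fragment) {
  for (field in c("label", "description", "display_mode", "renderer",
                  "ellipsis_limit", "numeric_format")) {
    if (is.null(explicit[[field]]) && !is.null(fragment[[field]])) {
      explicit[[field]] <- fragment[[field]]
    }
  }
  if (length(explicit$linkouts) == 0 && length(fragment$linkouts) > 0) {
    explicit$linkouts <- fragment$linkouts
  }
  explicit
}

normalize_renderer <- function(r, col_path) {
  path <- glue("{col_path}.renderer")
  if (!is.list(r)) config_error("'renderer' must be a mapping", path)
  kind <- scalar_chr(r$kind, "kind", path)
  if (!kind %in% RENDERER_KINDS) {
    config_error(glue("unknown renderer kind '{kind}'"), path)
  }
  switch(kind,
    plain = {
      check_keys(r, "kind", path)
      list(kind = "plain")
    },
    tick = {
      check_keys(r, c("kind", "domain", "aux_range"), path)
      list(kind = "tick",
           domain = normalize_domain(r$domain, path),
           aux_range = normalize_aux_range(r$aux_range, path))
    },
    bar = {
      check_keys(r, c("kind", "domain", "color_scale", "aux_range"), path)
      list(kind = "bar",
           domain = normalize_domain(r$domain, path),
           color_scale = if (!is.null(r$color_scale)) {
             normalize_scale(r$color_scale, glue("{path}.color_scale"))
           },
           aux_range = normalize_aux_range(r$aux_range, path))
    },
    heatmap = {
      check_keys(r, c("kind", "scale"), path)
      if (is.null(r$scale)) config_error("heatmap needs a 'scale'", path)
      list(kind = "heatmap",
           scale = normalize_scale(r$scale, glue("{path}.scale")))
    },
    pills = {
      check_keys(r, c("kind", "separator"), path)
      sep <- scalar_chr(r$separator, "separator", path, optional = TRUE) %||% ","
      if (nchar(sep) != 1) {
        config_error("pills 'separator' must be a single character", path)
      }
      list(kind = "pills", separator = sep)
    },
    custom_script = {
      check_keys(r, c("kind", "source"), path)
      list(kind = "custom_script",
           source = scalar_chr(r$source, "source", path))
    },
    custom_plot = {
      check_keys(r, c("kind", "spec"), path)
      if (!is.list(r$spec)) {
        config_error("custom_plot needs a 'spec' mapping", path)
      }
      list(kind = "custom_plot", spec = r$spec)
    }
  )
}

normalize_domain <- function(domain, path) {
  if (is.null(domain)) return(NULL)
  if (is.list(domain) && all(vapply(domain, is.numeric, logical(1)))) {
    domain <- unlist(domain)
  }
  if (!is.numeric(domain) || length(domain) != 2 || anyNA(domain)) {
    config_error("'domain' must be two numbers [min, max]", path)
  }
  as.numeric(domain)
}

normalize_aux_range <- function(aux, path) {
  if (is.null(aux)) return(NULL)
  aux <- unlist(aux)
  if (!is.character(aux) || length(aux) != 2) {
    config_error("'aux_range' must be two column names [low, high]", path)
  }
  as.character(aux)
}

normalize_scale <- function(s, path) {
  if (!is.list(s)) config_error("scale must be a mapping", path)
  check_keys(s, c("kind", "domain", "colors", "clamp"), path)
  kind <- scalar_chr(s$kind, "kind", path)
  if (!kind %in% c("linear", "categorical")) {
    config_error(glue("unknown scale kind '{kind}'"), path)
  }
  if (kind == "linear") {
    domain <- normalize_domain(s$domain, path)
    if (is.null(domain)) {
      config_error("linear scale needs a numeric 'domain' [min, max]", path)
    }
    colors <- unlist(s$colors)
    if (!is.character(colors) || length(colors) < 2) {
      config_error("linear scale needs >= 2 color anchors", path)
    }
    lapply(colors, parse_hex_color)
    list(kind = "linear", domain = domain, colors = as.character(colors),
         clamp = scalar_flag(s$clamp, "clamp", path, default = TRUE))
  } else {
    domain <- as.character(unlist(s$domain))
    if (length(domain) == 0) {
      config_error("categorical scale needs a 'domain' value set", path)
    }
    colors <- s$colors
    if (is.null(colors) || is.null(names(colors))) {
      config_error("categorical scale needs a 'colors' mapping", path)
    }
    colors <- vapply(colors, as.character, character(1))
    missing <- setdiff(domain, names(colors))
    if (length(missing) > 0) {
      config_error(glue("categorical scale misses a color for '{missing[1]}'"),
                   path)
    }
    lapply(colors, parse_hex_color)
    list(kind = "categorical", domain = domain, colors = as.list(colors),
         clamp = TRUE)
  }
}

#' @export
print.report_config <- function(x, ...) {
  cat(glue("<report_config> '{x$report_name}': ",
           "{length(x$datasets)} dataset(s), {length(x$views)} view(s), ",
           "default page size {x$default_page_size}\n"))
  invisible(x)
}

#' Serialize a normalized configuration back to YAML
#'
#' Emits YAML that reparses (via [load_config()]) to an equal configuration,
#' used for the provenance echo embedded in generated reports.
#'
#' @param config A `report_config`.
#' @return A single YAML string.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "report_config"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[!vapply(x, is.null, logical(1))]
    } else {
      x
    }
  }
  doc <- list(
    report_name = config$report_name,
    default_page_size = config$default_page_size,
    share_base_url = config$share_base_url,
    datasets = lapply(config$datasets, function(ds) {
      list(path = ds$path, format = ds$format, separator = ds$separator,
           has_header = ds$has_header,
           links = if (length(ds$links) > 0) {
             lapply(ds$links, function(l) {
               list(kind = l$kind, source_column = l$source_column,
                    target_view = l$target_view,
                    target_key_column = l$target_key_column,
                    detail_dataset = l$detail_dataset,
                    optional = l$optional)
             })
           })
    }),
    views = lapply(config$views, function(v) {
      list(dataset = v$dataset, description = v$description,
           page_size = v$page_size, render_kind = v$render_kind,
           columns = if (v$render_kind == "table" && length(v$columns) > 0) {
             lapply(v$columns, function(cs) {
               # spell-derived settings are serialized resolved AND with the
               # spell reference; on reparse the explicit settings win, so
               # the round trip is exact
               list(label = cs$label, description = cs$description,
                    display_mode = cs$display_mode, renderer = cs$renderer,
                    ellipsis_limit = cs$ellipsis_limit,
                    linkouts = if (length(cs$linkouts) > 0) cs$linkouts,
                    numeric_format = cs$numeric_format,
                    spell = cs$spell)
             })
           },
           plot_spec = v$plot_spec, html_body = v$html_body,
           show_line_numbers = v$show_line_numbers,
           extra_header_rows = if (v$extra_header_rows > 0) v$extra_header_rows)
    })
  )
  yaml::as.yaml(strip(doc), indent.mapping.sequence = TRUE)
}

# ---- cross-table validation -------------------------------------------------

issue_row <- function(path, message) {
  tibble(path = path, message = message)
}

#' Validate a configuration against loaded tables
#'
#' Returns all problems found as data (an empty tibble means valid): column
#' specifications naming absent columns, links to absent views or columns,
#' degenerate numeric domains (min >= max), and non-positive page sizes.
#'
#' @param config A `report_config`.
#' @param tables Named list of data frames, one per dataset id.
#' @return A tibble with columns `path` and `message`.
#' @export
validate_config <- function(config, tables) {
  stopifnot(inherits(config, "report_config"))
  issues <- list()
  push <- function(path, message) {
    issues[[length(issues) + 1]] <<- issue_row(path, message)
  }
  missing_tables <- setdiff(names(config$datasets), names(tables))
  if (length(missing_tables) > 0) {
    abort(glue("no table supplied for dataset '{missing_tables[1]}'"),
          class = "tabreport_type_error")
  }

  for (vid in names(config$views)) {
    view <- config$views[[vid]]
    tab <- tables[[view$dataset]]
    vpath <- glue("views.{vid}")
    if (!is.null(view$page_size) && view$page_size < 1) {
      push(glue("{vpath}.page_size"), "page_size must be >= 1")
    }
    if (view$render_kind != "table") next
    for (cn in names(view$columns)) {
      cs <- view$columns[[cn]]
      cpath <- glue("{vpath}.columns.{cn}")
      if (!cn %in% names(tab)) {
        push(cpath, glue("column '{cn}' is absent from dataset '{view$dataset}'"))
        next
      }
      r <- cs$renderer
      if (r$kind %in% c("tick", "bar") && !is.null(r$domain) &&
          r$domain[1] >= r$domain[2]) {
        push(glue("{cpath}.renderer.domain"),
             glue("degenerate domain [{r$domain[1]}, {r$domain[2]}]"))
      }
      if (r$kind == "heatmap" && r$scale$kind == "linear" &&
          r$scale$domain[1] >= r$scale$domain[2]) {
        push(glue("{cpath}.renderer.scale.domain"),
             glue("degenerate domain [{r$scale$domain[1]}, {r$scale$domain[2]}]"))
      }
      if (r$kind == "bar" && !is.null(r$color_scale) &&
          r$color_scale$kind == "linear" &&
          r$color_scale$domain[1] >= r$color_scale$domain[2]) {
        push(glue("{cpath}.renderer.color_scale.domain"),
             glue("degenerate domain"))
      }
      if (r$kind %in% c("tick", "bar") && !is.null(r$aux_range)) {
        absent <- setdiff(r$aux_range, names(tab))
        if (length(absent) > 0) {
          push(glue("{cpath}.renderer.aux_range"),
               glue("aux_range column '{absent[1]}' is absent"))
        }
      }
      for (lo in cs$linkouts) {
        refs <- linkout_placeholders(lo$url_template)
        absent <- setdiff(setdiff(refs, "value"), names(tab))
        if (length(absent) > 0) {
          push(glue("{cpath}.linkouts"),
               glue("linkout '{lo$name}' references absent column '{absent[1]}'"))
        }
      }
    }
  }

  for (ds_id in names(config$datasets)) {
    ds <- config$datasets[[ds_id]]
    tab <- tables[[ds_id]]
    for (link in ds$links) {
      lpath <- glue("datasets.{ds_id}.links.{link$name}")
      if (!link$source_column %in% names(tab)) {
        push(lpath, glue("source_column '{link$source_column}' is absent"))
      }
      if (link$kind == "row_link") {
        if (!link$target_view %in% names(config$views)) {
          push(lpath, glue("target view '{link$target_view}' does not exist"))
          next
        }
        target_ds <- config$views[[link$target_view]]$dataset
        if (!link$target_key_column %in% names(tables[[target_ds]])) {
          push(lpath,
               glue("target_key_column '{link$target_key_column}' is absent ",
                    "from dataset '{target_ds}'"))
        }
      }
    }
  }

  if (length(issues) == 0) {
    tibble(path = character(0), message = character(0))
  } else {
    bind_rows(issues)
  }
}

# ---- display-mode bookkeeping ----------------------------------------------

#' Partition a view's columns by display mode
#'
#' Display modes map onto interface groups: `normal` columns are shown and
#' togglable; `detail` columns unfold per row; `available` columns are
#' togglable but start hidden; `pinned` columns are always shown and absent
#' from the toggle interface; `hidden` columns are excluded from every
#' output. Original column order is preserved within each group.
#'
#' @param view A view specification from a `report_config`, with its `columns`
#'   mapping covering the columns to partition (columns of the table not named
#'   in the view are treated as `normal`).
#' @param table_columns Optional character vector of the dataset's columns, to
#'   include unconfigured columns as `normal`.
#' @return A list with character vectors `main`, `detail`, `selectable`,
#'   `always_shown`, and `excluded`.
#' @export
partition_columns <- function(view, table_columns = NULL) {
  cols <- names(view$columns)
  if (!is.null(table_columns)) {
    cols <- c(cols, setdiff(table_columns, cols))
    cols <- cols[order(match(cols, table_columns))]
  }
  modes <- vapply(cols, function(cn) {
    cs <- view$columns[[cn]]
    if (is.null(cs)) "normal" else cs$display_mode
  }, character(1))
  list(
    main = cols[modes %in% c("normal", "pinned")],
    detail = cols[modes == "detail"],
    selectable = cols[modes %in% c("normal", "available")],
    always_shown = cols[modes == "pinned"],
    excluded = cols[modes == "hidden"]
  )
}
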