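# Report bundle assembly: one HTML file per page per view, per-column index
# documents, compressed script payloads, vendored runtime assets, XLSX
# export, and the share-row viewer. Output is deterministic: identical
# inputs produce byte-identical bundles (no timestamps anywhere).

SHARE_PARAM <- "row"

#' Generate a report from a configuration
#'
#' End-to-end pipeline: load and validate the configuration, read every
#' dataset, resolve links, paginate, compress, and write the self-contained
#' bundle. Generation is atomic — on any failure no partial bundle is left
#' behind.
#'
#' @param config A `report_config`, YAML text, or the path of a YAML file.
#' @param output_dir Directory to create the bundle in.
#' @param tables Optional named list of tables (dataset id -> data frame);
#'   read from the dataset paths when omitted.
#' @param page_size Optional override of the configuration's
#'   `default_page_size`.
#' @param base_dir Directory dataset paths are resolved against (defaults to
#'   the config file's directory, or the working directory).
#' @return A `report_bundle`: list with `root` and a `manifest` tibble.
#' @export
generate_report <- function(config, output_dir, tables = NULL,
                            page_size = NULL, base_dir = NULL) {
  if (!inherits(config, "report_config")) {
    if (is.character(config) && length(config) == 1 &&
        !grepl("\n", config) && file.exists(config)) {
      base_dir <- base_dir %||% dirname(config)
    }
    config <- load_config(config)
  }
  base_dir <- base_dir %||% "."
  if (!is.null(page_size)) {
    stopifnot(is_count(page_size))
    config$default_page_size <- as.integer(page_size)
  }
  if (is.null(tables)) {
    tables <- lapply(config$datasets, function(ds) {
      ds$path <- if (file.exists(ds$path)) ds$path else file.path(base_dir, ds$path)
      read_table(ds)
    })
  }
  tables <- lapply(tables, as_report_table)
  issues <- validate_config(config, tables)
  if (nrow(issues) > 0) {
    msgs <- paste(sprintf("- %s: %s", issues$path, issues$message),
                  collapse = "\n")
    abort(glue("configuration has {nrow(issues)} issue(s):\n{msgs}"),
          class = "tabreport_validation_error")
  }
  render_report(config, tables, output_dir)
}

#' Assemble and write the report bundle
#'
#' Lower-level entry point of the emission stage: assumes the configuration
#' already validates against `tables`. Builds into a temporary directory and
#' moves the finished bundle into place.
#'
#' @inheritParams generate_report
#' @return A `report_bundle`.
#' @export
render_report <- function(config, tables, output_dir) {
  stopifnot(inherits(config, "report_config"))
  staging <- tempfile("tabreport_build_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  manifest <- build_bundle(config, tables, staging)

  if (dir.exists(output_dir)) {
    unlink(output_dir, recursive = TRUE)
  }
  dir.create(dirname(output_dir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(staging, output_dir)) {
    # cross-device fallback
    dir.create(output_dir, recursive = TRUE)
    for (f in manifest$file) {
      dir.create(dirname(file.path(output_dir, f)), recursive = TRUE,
                 showWarnings = FALSE)
      file.copy(file.path(staging, f), file.path(output_dir, f),
                overwrite = TRUE)
    }
  }
  structure(list(root = output_dir, manifest = manifest),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(glue("<report_bundle> {x$root}: {nrow(x$manifest)} files\n"))
  invisible(x)
}

# ---- internal assembly ------------------------------------------------------

build_bundle <- function(config, tables, root) {
  manifest <- list()
  emit <- function(rel_path, content, role) {
    full <- file.path(root, rel_path)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    con <- file(full, "wb")
    writeBin(charToRaw(enc2utf8(content)), con)
    close(con)
    manifest[[length(manifest) + 1]] <<- tibble(file = rel_path, role = role)
  }

  # Per-view plan: mode, page size, display table (extra header rows
  # removed), pagination.
  views <- config$views
  plans <- list()
  for (vid in names(views)) {
    view <- views[[vid]]
    tab <- tables[[view$dataset]]
    if (view$render_kind == "table") {
      excluded <- partition_columns(view, names(tab))$excluded
      if (length(excluded) > 0) {
        tab <- tab[, setdiff(names(tab), excluded), drop = FALSE]
      }
      header_extra <- list()
      if (view$extra_header_rows > 0) {
        take <- seq_len(min(view$extra_header_rows, nrow(tab)))
        header_extra <- lapply(take, function(i) {
          unname(as.list(canonical_text_row(tab[i, , drop = FALSE])))
        })
        tab <- tab[-take, , drop = FALSE]
      }
      size <- view$page_size %||% config$default_page_size
      mode <- choose_mode(nrow(tab), size)
      eff_size <- if (mode == "in_memory") max(nrow(tab), 1L) else size
      plans[[vid]] <- list(view = view, table = tab, mode = mode,
                           page_size = eff_size,
                           configured_page_size = size,
                           header_extra = header_extra)
    } else {
      plans[[vid]] <- list(view = view, table = tab, mode = "single",
                           page_size = max(nrow(tab), 1L),
                           configured_page_size = config$default_page_size,
                           header_extra = list())
    }
  }

  # Hierarchical subtables become generated child views.
  child_views <- list()
  for (ds_id in names(config$datasets)) {
    ds <- config$datasets[[ds_id]]
    parent_view_ids <- names(views)[vapply(views, function(v) {
      v$dataset == ds_id && v$render_kind == "table"
    }, logical(1))]
    for (link in ds$links) {
      if (link$kind != "subtable_link") next
      detail <- tables[[link$detail_dataset]]
      for (pvid in parent_view_ids) {
        split <- split_subtables(plans[[pvid]]$table, link$source_column,
                                 detail, view_id = pvid)
        child_views[[length(child_views) + 1]] <- list(
          parent = pvid, link = link, split = split
        )
        for (i in seq_len(nrow(split))) {
          cvid <- split$child_view[i]
          plans[[cvid]] <- list(
            view = list(id = cvid, dataset = link$detail_dataset,
                        description = NULL, page_size = NULL,
                        render_kind = "table", columns = list(),
                        plot_spec = NULL, html_body = NULL,
                        show_line_numbers = FALSE, extra_header_rows = 0L),
            table = split$table[[i]], mode = "in_memory",
            page_size = max(nrow(split$table[[i]]), 1L),
            configured_page_size = config$default_page_size,
            header_extra = list(),
            generated = TRUE, parent = pvid, key = split$key[i]
          )
        }
      }
    }
  }

  page_sizes <- vapply(plans, function(p) p$page_size, integer(1))

  # Row-link resolution per dataset, against the target views' pagination.
  link_res <- list()
  for (vid in names(plans)) {
    plan <- plans[[vid]]
    if (plan$view$render_kind != "table" || isTRUE(plan$generated)) next
    ds <- config$datasets[[plan$view$dataset]]
    row_links <- Filter(function(l) l$kind == "row_link", ds$links)
    if (length(row_links) == 0) next
    target_tables <- list()
    for (l in row_links) {
      target_tables[[l$target_view]] <- plans[[l$target_view]]$table
    }
    link_res[[vid]] <- resolve_row_links(
      plan$table, row_links, target_tables,
      as.list(page_sizes[vapply(row_links, function(l) l$target_view,
                                character(1))])
    )
  }
  # Subtable links per parent view: row -> child view path.
  subtable_res <- list()
  for (cv in child_views) {
    pvid <- cv$parent
    keys <- canonical_text(plans[[pvid]]$table[[cv$link$source_column]])
    child <- cv$split$child_view[match(keys, cv$split$key)]
    n_rows <- vapply(cv$split$table, nrow, integer(1))[match(keys, cv$split$key)]
    subtable_res[[pvid]] <- c(subtable_res[[pvid]], list(tibble(
      row = seq_along(keys), link = cv$link$name,
      child_view = ifelse(is.na(child), NA_character_, child),
      child_rows = ifelse(is.na(n_rows), 0L, n_rows)
    )))
  }

  # Emit all view pages.
  nav <- navigation_entries(config, plans)
  for (vid in names(plans)) {
    plan <- plans[[vid]]
    view <- plan$view
    if (view$render_kind == "table") {
      emit_table_view(config, plans, vid, link_res[[vid]],
                      subtable_res[[vid]], nav, emit)
    } else if (view$render_kind == "plot") {
      emit_plot_view(config, plan, nav, emit)
    } else {
      emit_html_view(config, plan, nav, emit)
    }
  }

  # Landing page, assets, export, share viewer.
  emit("index.html", landing_page(config, plans, nav), "entry")
  asset_files <- bundle_assets(root)
  for (f in asset_files) {
    manifest[[length(manifest) + 1]] <- tibble(file = f, role = "asset")
  }
  emit("share/viewer.html", share_viewer_page(config), "asset")
  table_views <- Filter(function(p) p$view$render_kind == "table" &&
                          !isTRUE(p$generated), plans)
  xlsx_path <- file.path(root, "export", "report.xlsx")
  dir.create(dirname(xlsx_path), recursive = TRUE, showWarnings = FALSE)
  export_xlsx(lapply(table_views, function(p) p$table), xlsx_path)
  manifest[[length(manifest) + 1]] <- tibble(file = "export/report.xlsx",
                                             role = "export")

  bind_rows(manifest)
}

canonical_text_row <- function(row) {
  vapply(row, function(col) canonical_text(col), character(1))
}

navigation_entries <- function(config, plans) {
  top <- names(plans)[!vapply(plans, function(p) isTRUE(p$generated),
                              logical(1))]
  tibble(
    view = top,
    file = sprintf("%s/page_1.html", slugify(top)),
    label = top
  )
}

# Effective renderer for a column: defaults resolved against observed data.
resolve_renderer <- function(cs, column_values) {
  r <- cs$renderer
  if (r$kind %in% c("tick", "bar") && is.null(r$domain)) {
    x <- suppressWarnings(as.numeric(column_values))
    x <- x[!is.na(x)]
    r$domain <- if (length(x) > 0 && min(x) < max(x)) c(min(x), max(x))
                else c(0, 1)
  }
  r
}

view_column_plan <- function(view, tab) {
  lapply(names(tab), function(cn) {
    cs <- view$columns[[cn]]
    if (is.null(cs)) {
      cs <- list(column = cn, label = cn, description = NULL,
                 display_mode = "normal", renderer = list(kind = "plain"),
                 ellipsis_limit = NULL, linkouts = list(),
                 numeric_format = "auto")
    }
    cs$renderer <- resolve_renderer(cs, tab[[cn]])
    cs$description_html <- if (!is.null(cs$description)) {
      render_markdown(cs$description)
    }
    cs$type <- if (is.numeric(tab[[cn]])) "numeric"
               else if (is.logical(tab[[cn]])) "boolean"
               else "text"
    cs$histogram <- histogram_payload(tab[[cn]])
    cs
  })
}

histogram_payload <- function(values) {
  h <- column_histogram(values)
  if (attr(h, "kind") == "numeric") {
    list(kind = "numeric", lo = h$lo, hi = h$hi, count = h$count,
         n = attr(h, "n"))
  } else {
    list(kind = "nominal", value = h$value, count = h$count, n = attr(h, "n"))
  }
}

render_markdown <- function(text) {
  html <- commonmark::markdown_html(text, extensions = TRUE)
  gsub("\\$([^$]+)\\$", '<span class="math">\\1</span>', html)
}

page_context_json <- function(config, plans, vid, page, n_pages, links_page,
                              subtables_page, columns_plan, plan) {
  view <- plan$view
  groups <- if (view$render_kind == "table") {
    partition_columns(view, names(plan$table))
  }
  ctx <- list(
    report_name = config$report_name,
    view = vid,
    page = page$page_number,
    n_pages = n_pages,
    page_size = plan$page_size,
    start_row = page$start,
    total_rows = nrow(plan$table),
    mode = plan$mode,
    show_line_numbers = isTRUE(view$show_line_numbers),
    header_extra = plan$header_extra,
    columns = lapply(columns_plan, function(cs) {
      list(name = cs$column, label = cs$label,
           description = cs$description_html,
           display_mode = cs$display_mode, renderer = cs$renderer,
           ellipsis_limit = cs$ellipsis_limit, linkouts = cs$linkouts,
           numeric_format = cs$numeric_format, type = cs$type,
           histogram = cs$histogram)
    }),
    groups = groups,
    links = links_page,
    subtables = subtables_page,
    share = list(base_url = config$share_base_url %||%
                   "../share/viewer.html",
                 param = SHARE_PARAM),
    categorical_cutoff = categorical_cutoff()
  )
  as.character(jsonlite::toJSON(ctx, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

js_escape_payload <- function(payload) {
  payload <- gsub("\\", "\\\\", payload, fixed = TRUE)
  payload <- gsub("\"", "\\\"", payload, fixed = TRUE)
  payload <- gsub(intToUtf8(0x2028), "\\u2028", payload, fixed = TRUE)
  gsub(intToUtf8(0x2029), "\\u2029", payload, fixed = TRUE)
}

html_head <- function(title, depth) {
  prefix <- paste(rep("../", depth), collapse = "")
  paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n",
    "<meta charset=\"utf-8\"/>\n",
    "<meta name=\"viewport\" content=\"width=device-width, initial-scale=1\"/>\n",
    "<title>", html_escape(title), "</title>\n",
    "<link rel=\"stylesheet\" href=\"", prefix, "static/report.css\"/>\n",
    "</head>\n<body>\n"
  )
}

nav_html <- function(nav, depth, active = NULL) {
  prefix <- paste(rep("../", depth), collapse = "")
  items <- vapply(seq_len(nrow(nav)), function(i) {
    cls <- if (!is.null(active) && nav$view[i] == active) {
      " class=\"active\""
    } else {
      ""
    }
    sprintf("<a%s href=\"%s%s\">%s</a>", cls, prefix, nav$file[i],
            html_escape(nav$label[i]))
  }, character(1))
  paste0("<nav class=\"views\"><a href=\"", prefix,
         "index.html\">Overview</a>", paste(items, collapse = ""),
         "</nav>\n")
}

emit_table_view <- function(config, plans, vid, links, subtables, nav, emit) {
  plan <- plans[[vid]]
  view <- plan$view
  tab <- plan$table
  slug <- slugify(vid)
  pages <- paginate(tab, plan$page_size)
  n_pages <- length(pages)
  columns_plan <- view_column_plan(view, tab)

  index_plan <- NULL
  if (plan$mode == "partitioned") {
    index <- build_search_index(tab, plan$page_size)
    index_plan <- plan_index_pages(index, vid)
    for (i in seq_len(nrow(index_plan))) {
      emit(index_plan$file[i],
           index_document(config, vid, index_plan$column[i],
                          index_plan$payload[[i]], n_pages, nav),
           "index page")
    }
  }

  for (page in pages) {
    rows_abs <- if (nrow(page$rows) > 0) {
      page$start:(page$start + nrow(page$rows) - 1L)
    } else {
      integer(0)
    }
    links_page <- if (!is.null(links) && nrow(links) > 0) {
      pl <- links[links$row %in% rows_abs, , drop = FALSE]
      pl$row <- pl$row - page$start + 1L
      lapply(split(pl, pl$row), function(d) {
        stats::setNames(lapply(seq_len(nrow(d)), function(i) {
          if (!d$resolved[i]) return(NULL)
          list(view = d$target_view[i], page = d$page[i],
               offset = d$offset[i])
        }), d$link)
      })
    } else {
      stats::setNames(list(), character(0))
    }
    subtables_page <- if (!is.null(subtables)) {
      st <- bind_rows(subtables)
      st <- st[st$row %in% rows_abs, , drop = FALSE]
      st$row <- st$row - page$start + 1L
      lapply(split(st, st$row), function(d) {
        stats::setNames(lapply(seq_len(nrow(d)), function(i) {
          if (is.na(d$child_view[i])) return(NULL)
          list(view = d$child_view[i], rows = d$child_rows[i])
        }), d$link)
      })
    } else {
      stats::setNames(list(), character(0))
    }

    payload <- compress_table_payload(page$rows, name = vid)
    payload_file <- sprintf("data/%s/%d.js", slug, page$page_number)
    emit(payload_file,
         sprintf("window.tabreportData = window.tabreportData || {};\nwindow.tabreportData[\"%s/%d\"] = \"%s\";\n",
                 slug, page$page_number, js_escape_payload(payload$payload)),
         "payload")

    ctx <- page_context_json(config, plans, vid, page, n_pages, links_page,
                             subtables_page, columns_plan, plan)
    description <- if (!is.null(view$description)) {
      sprintf("<div class=\"view-description\">%s</div>\n",
              render_markdown(view$description))
    } else {
      ""
    }
    pager <- if (n_pages > 1) {
      entries <- vapply(seq_len(n_pages), function(k) {
        if (k == page$page_number) {
          sprintf("<span class=\"current\">%d</span>", k)
        } else {
          sprintf("<a href=\"page_%d.html\">%d</a>", k, k)
        }
      }, character(1))
      idx_links <- if (!is.null(index_plan)) {
        paste0("<details class=\"search\"><summary>Search</summary><ul>",
               paste(sprintf("<li><a href=\"%s\" target=\"index_frame\">%s</a></li>",
                             basename(index_plan$file),
                             html_escape(index_plan$column)),
                     collapse = ""),
               "</ul><iframe name=\"index_frame\" class=\"index-frame\"></iframe></details>")
      } else {
        ""
      }
      paste0("<div class=\"pager\">Pages: ", paste(entries, collapse = " "),
             "</div>", idx_links)
    } else {
      ""
    }
    body <- paste0(
      html_head(sprintf("%s — %s", config$report_name, vid), 1),
      nav_html(nav, 1, active = if (isTRUE(plan$generated)) plan$parent else vid),
      sprintf("<h1>%s</h1>\n", html_escape(vid)),
      if (isTRUE(plan$generated)) {
        sprintf("<p class=\"subtable-note\">Detail rows for <code>%s</code>. <a href=\"../%s/page_1.html\">Back</a></p>\n",
                html_escape(plan$key), slugify(plan$parent))
      } else {
        ""
      },
      description,
      pager,
      "<div id=\"table-root\"></div>\n",
      sprintf("<script>window.tabreportContext = %s;</script>\n", ctx),
      sprintf("<script src=\"../data/%s/%d.js\"></script>\n", slug,
              page$page_number),
      "<script src=\"../static/report.js\"></script>\n",
      "<script>tabreport.renderPage();</script>\n",
      "</body>\n</html>\n"
    )
    emit(sprintf("%s/page_%d.html", slug, page$page_number), body,
         "view page")
  }
}

index_document <- function(config, vid, column, payload, n_pages, nav) {
  paste0(
    html_head(sprintf("Index of %s — %s", column, vid), 1),
    sprintf("<h1>Search index: %s</h1>\n", html_escape(column)),
    "<p>Filter the values, then follow an occurrence to open its page with the row highlighted.</p>\n",
    "<input id=\"index-filter\" type=\"search\" placeholder=\"Filter values…\"/>\n",
    "<div id=\"index-root\"></div>\n",
    sprintf("<script>window.tabreportIndexPayload = \"%s\"; window.tabreportIndexView = \"%s\";</script>\n",
            js_escape_payload(payload$payload), slugify(vid)),
    "<script src=\"../static/report.js\"></script>\n",
    "<script>tabreport.renderIndex();</script>\n",
    "</body>\n</html>\n"
  )
}

emit_plot_view <- function(config, plan, nav, emit) {
  vid <- plan$view$id
  slug <- slugify(vid)
  payload <- compress_table_payload(plan$table, name = vid)
  emit(sprintf("data/%s/1.js", slug),
       sprintf("window.tabreportData = window.tabreportData || {};\nwindow.tabreportData[\"%s/1\"] = \"%s\";\n",
               slug, js_escape_payload(payload$payload)),
       "payload")
  spec_json <- as.character(jsonlite::toJSON(plan$view$plot_spec,
                                             auto_unbox = TRUE, digits = NA))
  body <- paste0(
    html_head(sprintf("%s — %s", config$report_name, vid), 1),
    nav_html(nav, 1, active = vid),
    sprintf("<h1>%s</h1>\n", html_escape(vid)),
    if (!is.null(plan$view$description)) {
      sprintf("<div class=\"view-description\">%s</div>\n",
              render_markdown(plan$view$description))
    } else {
      ""
    },
    "<div id=\"plot-root\"></div>\n",
    sprintf("<script>window.tabreportPlotSpec = %s; window.tabreportPlotView = \"%s\";</script>\n",
            spec_json, slug),
    sprintf("<script src=\"../data/%s/1.js\"></script>\n", slug),
    "<script src=\"../static/report.js\"></script>\n",
    "<script src=\"../static/plot-viewer.js\"></script>\n",
    "<script>tabreportPlotViewer.render();</script>\n",
    "</body>\n</html>\n"
  )
  emit(sprintf("%s/page_1.html", slug), body, "view page")
}

emit_html_view <- function(config, plan, nav, emit) {
  vid <- plan$view$id
  slug <- slugify(vid)
  body <- paste0(
    html_head(sprintf("%s — %s", config$report_name, vid), 1),
    nav_html(nav, 1, active = vid),
    sprintf("<h1>%s</h1>\n", html_escape(vid)),
    "<div class=\"html-view\">\n",
    plan$view$html_body,  # embedded verbatim by design
    "\n</div>\n</body>\n</html>\n"
  )
  emit(sprintf("%s/page_1.html", slug), body, "view page")
}

landing_page <- function(config, plans, nav) {
  top <- nav$view
  rows <- vapply(top, function(vid) {
    plan <- plans[[vid]]
    kind <- plan$view$render_kind
    detail <- if (kind == "table") {
      sprintf("%d rows, %s mode", nrow(plan$table),
              gsub("_", "-", plan$mode))
    } else {
      kind
    }
    sprintf("<li><a href=\"%s\">%s</a> <span class=\"meta\">(%s)</span></li>",
            nav$file[nav$view == vid], html_escape(vid), detail)
  }, character(1))
  paste0(
    html_head(config$report_name, 0),
    nav_html(nav, 0),
    sprintf("<h1>%s</h1>\n", html_escape(config$report_name)),
    "<ul class=\"view-list\">\n", paste(rows, collapse = "\n"), "\n</ul>\n",
    "<p><a href=\"export/report.xlsx\">Download as XLSX</a></p>\n",
    "<details class=\"config-echo\"><summary>Configuration</summary><pre>",
    html_escape(serialize_config(config)),
    "</pre></details>\n",
    "</body>\n</html>\n"
  )
}

share_viewer_page <- function(config) {
  paste0(
    html_head("Shared row", 1),
    "<h1>Shared row</h1>\n",
    "<p>This page decodes a table row carried in its URL; no data leaves the browser.</p>\n",
    "<div id=\"share-root\"></div>\n",
    "<script src=\"../static/report.js\"></script>\n",
    "<script>tabreport.renderSharedRow();</script>\n",
    "</body>\n</html>\n"
  )
}

# ---- share URLs -------------------------------------------------------------

#' Encode one table row into a shareable URL
#'
#' Serializes the row (column names and canonical cell texts) as JSON,
#' compresses it with the URI-component LZ-string variant, and appends it as
#' a single query parameter to the base URL. `decode_share_url()` is the
#' exact inverse.
#'
#' @param row A one-row data frame or named list of cells.
#' @param base_url Viewer page URL; defaults to the bundled share viewer.
#' @return The share URL.
#' @export
encode_share_url <- function(row, base_url = "share/viewer.html") {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1)
    row <- as.list(row)
  }
  doc <- list(columns = names(row),
              cells = unname(lapply(row, function(v) canonical_text(v))))
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  payload <- lz_compress(json, "uri_component")$payload
  sprintf("%s?%s=%s", base_url, SHARE_PARAM, payload)
}

#' @rdname encode_share_url
#' @param url A URL produced by `encode_share_url()`.
#' @export
decode_share_url <- function(url) {
  m <- regmatches(url, regexec(sprintf("[?&]%s=([^&#]*)", SHARE_PARAM), url))[[1]]
  if (length(m) < 2) {
    abort("URL carries no share payload", class = "tabreport_corruption_error")
  }
  json <- lz_decompress(m[2], alphabet = "uri_component")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  stats::setNames(
    vapply(doc$cells, as.character, character(1)),
    vapply(doc$columns, as.character, character(1))
  )
}

# ---- self-containment -------------------------------------------------------

#' Scan a bundle for external references
#'
#' Finds every fetchable reference (`script src`, `link href`, `img src`,
#' `iframe src`, CSS `url(...)`) and every plain anchor pointing at an
#' absolute `http(s)://` or protocol-relative URL. Anchors marked as
#' linkouts or share links (declared in the configuration) are exempt — they
#' are the only sanctioned external references in a bundle.
#'
#' @param root Bundle root directory.
#' @return A tibble with columns `file`, `kind`, `url` (empty when the
#'   bundle is fully self-contained).
#' @export
scan_external_refs <- function(root) {
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  files <- files[grepl("\\.(html|js|css)$", files)]
  hits <- list()
  is_external <- function(url) grepl("^(https?:)?//", url)
  for (f in sort(files)) {
    text <- paste(readLines(file.path(root, f), warn = FALSE,
                            encoding = "UTF-8"), collapse = "\n")
    for (pat in c(
      "<script[^>]*\\ssrc=\"([^\"]+)\"", "<link[^>]*\\shref=\"([^\"]+)\"",
      "<img[^>]*\\ssrc=\"([^\"]+)\"", "<iframe[^>]*\\ssrc=\"([^\"]+)\""
    )) {
      m <- regmatches(text, gregexpr(pat, text))[[1]]
      urls <- gsub(pat, "\\1", m)
      for (u in urls[is_external(urls)]) {
        hits[[length(hits) + 1]] <- tibble(file = f, kind = "fetch", url = u)
      }
    }
    if (grepl("\\.css$", f)) {
      m <- regmatches(text, gregexpr("url\\(([^)]+)\\)", text))[[1]]
      urls <- gsub("url\\(([^)]+)\\)", "\\1", m)
      urls <- gsub("^['\"]|['\"]$", "", urls)
      for (u in urls[is_external(urls)]) {
        hits[[length(hits) + 1]] <- tibble(file = f, kind = "css", url = u)
      }
    }
    anchor_pat <- "<a\\s[^>]*>"
    m <- regmatches(text, gregexpr(anchor_pat, text))[[1]]
    for (tag in m) {
      href <- regmatches(tag, regexec("href=\"([^\"]+)\"", tag))[[1]]
      if (length(href) < 2 || !is_external(href[2])) next
      if (grepl("class=\"[^\"]*(linkout|share-link)", tag)) next
      hits[[length(hits) + 1]] <- tibble(file = f, kind = "anchor",
                                         url = href[2])
    }
  }
  if (length(hits) == 0) {
    tibble(file = character(0), kind = character(0), url = character(0))
  } else {
    bind_rows(hits)
  }
}
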