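# Spells: reusable, parameterized column-configuration templates, applied by
# identifier with a `with:` parameter mapping. Resolution is plain textual
# placeholder substitution (`<param>` tokens in the body's YAML), after which
# the body must parse as a valid column-specification fragment. Explicit
# column settings always win over spell-provided ones.

#' Load a spell by identifier
#'
#' Spell files are YAML documents with `identifier:`, `parameters:` (a
#' mapping of parameter name to default value; a null default marks the
#' parameter required), and `body:` (a column-specification fragment whose
#' scalars may contain `<param>` placeholders). Files are searched as
#' `<identifier>.yaml` in `spell_dirs` first, then among the package's
#' built-in spells.
#'
#' @param identifier Spell name.
#' @param spell_dirs Extra directories to search, in order.
#' @return A `spell` object.
#' @export
load_spell <- function(identifier, spell_dirs = character(0)) {
  if (!grepl("^[A-Za-z0-9_-]+$", identifier)) {
    abort(glue("invalid spell identifier '{identifier}'"),
          class = "tabreport_config_error")
  }
  dirs <- c(spell_dirs, system.file("spells", package = "tabreport"))
  for (dir in dirs) {
    candidate <- file.path(dir, paste0(identifier, ".yaml"))
    if (file.exists(candidate)) {
      return(parse_spell(paste(readLines(candidate, warn = FALSE,
                                         encoding = "UTF-8"),
                               collapse = "\n"),
                         identifier))
    }
  }
  abort(glue("spell '{identifier}' not found in any spell directory"),
        class = "tabreport_config_error")
}

#' Parse a spell document
#'
#' @param yaml_text The spell file's YAML text.
#' @param identifier Expected identifier (checked against the document).
#' @return A `spell` object with fields `identifier`, `parameters` (named
#'   list; `NULL` default = required), and `body_yaml` (the body as YAML
#'   text, placeholders intact).
#' @export
parse_spell <- function(yaml_text, identifier = NULL) {
  doc <- tryCatch(yaml::yaml.load(yaml_text), error = function(e) {
    abort(glue("spell is not valid YAML: {conditionMessage(e)}"),
          class = "tabreport_parse_error")
  })
  check_keys(doc, c("identifier", "parameters", "body"), "spell")
  id <- scalar_chr(doc$identifier, "identifier", "spell")
  if (!is.null(identifier) && id != identifier) {
    abort(glue("spell file declares identifier '{id}', expected '{identifier}'"),
          class = "tabreport_config_error")
  }
  params <- doc$parameters %||% list()
  if (length(params) > 0 && is.null(names(params))) {
    abort("spell 'parameters' must be a mapping", class = "tabreport_config_error")
  }
  if (is.null(doc$body) || !is.list(doc$body)) {
    abort("spell needs a 'body' mapping", class = "tabreport_config_error")
  }
  body_yaml <- yaml::as.yaml(doc$body, indent.mapping.sequence = TRUE)
  declared <- names(params)
  used <- spell_placeholders(body_yaml)
  undeclared <- setdiff(used, declared)
  if (length(undeclared) > 0) {
    abort(glue("spell '{id}' body uses undeclared parameter ",
               "'<{undeclared[1]}>'"),
          class = "tabreport_config_error")
  }
  structure(list(identifier = id, parameters = params, body_yaml = body_yaml),
            class = "spell")
}

spell_placeholders <- function(text) {
  m <- gregexpr("<([A-Za-z_][A-Za-z0-9_]*)>", text)
  tokens <- unlist(regmatches(text, m))
  unique(gsub("^<|>$", "", tokens))
}

#' Resolve a spell into a column-specification fragment
#'
#' Substitutes each `<param>` placeholder in the spell body with the supplied
#' (or default) value, reparses the body, and validates it as a column
#' specification fragment. `with` values must be scalars.
#'
#' @param spell A `spell` object (or an identifier to load).
#' @param with_params Named list of parameter values.
#' @param column Column name the fragment is for (used in error messages and
#'   as the fragment's column).
#' @param spell_dirs Passed to [load_spell()] when `spell` is an identifier.
#' @return A column-specification fragment (same shape as entries of a
#'   view's `columns`).
#' @export
resolve_spell <- function(spell, with_params = list(), column = "column",
                          spell_dirs = character(0)) {
  if (is.character(spell)) spell <- load_spell(spell, spell_dirs)
  stopifnot(inherits(spell, "spell"))
  with_params <- with_params %||% list()
  declared <- names(spell$parameters)
  unknown <- setdiff(names(with_params), declared)
  if (length(unknown) > 0) {
    abort(glue("spell '{spell$identifier}': unknown parameter ",
               "'{unknown[1]}' in 'with'"),
          class = "tabreport_config_error")
  }
  values <- spell$parameters
  for (p in names(with_params)) values[[p]] <- with_params[[p]]
  required_missing <- declared[vapply(values, is.null, logical(1))]
  if (length(required_missing) > 0) {
    abort(glue("spell '{spell$identifier}': required parameter ",
               "'{required_missing[1]}' not supplied"),
          class = "tabreport_config_error")
  }
  bad <- names(values)[!vapply(values, function(v) {
    is.atomic(v) && length(v) == 1 && !is.na(v)
  }, logical(1))]
  if (length(bad) > 0) {
    abort(glue("spell '{spell$identifier}': parameter '{bad[1]}' must be ",
               "a scalar"),
          class = "tabreport_config_error")
  }

  body <- spell$body_yaml
  for (p in names(values)) {
    v <- values[[p]]
    formatted <- format_spell_value(v)
    token <- paste0("<", p, ">")
    if (is.numeric(v) || is.logical(v)) {
      # Unquote placeholders holding non-string scalars so the substituted
      # body parses them as numbers/booleans.
      body <- gsub(paste0("'", token, "'"), formatted, body, fixed = TRUE)
      body <- gsub(paste0("\"", token, "\""), formatted, body, fixed = TRUE)
    }
    body <- gsub(token, formatted, body, fixed = TRUE)
  }
  fragment <- tryCatch(yaml::yaml.load(body), error = function(e) {
    abort(glue("spell '{spell$identifier}': body is invalid after ",
               "substitution: {conditionMessage(e)}"),
          class = "tabreport_config_error")
  })
  normalize_column(fragment, column, glue("spell.{spell$identifier}"),
                   character(0), allow_spell = FALSE)
}

format_spell_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(canonical_text(v))
  as.character(v)
}

#' @export
print.spell <- function(x, ...) {
  params <- if (length(x$parameters) > 0) {
    paste(names(x$parameters), collapse = ", ")
  } else {
    "none"
  }
  cat(glue("<spell> '{x$identifier}', parameters: {params}\n"))
  invisible(x)
}
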