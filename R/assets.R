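# Vendored runtime assets. The client-side runtime is hand-written and
# dependency-free so that bundles stay fully self-contained; assets are
# installed with the package and copied verbatim (deterministically) into
# every bundle's static/ directory.

runtime_asset_names <- function() {
  c("report.css", "report.js", "plot-viewer.js")
}

#' Copy the embedded runtime assets into a bundle
#'
#' Writes the stylesheet, the client-side runtime (payload decompression,
#' rendering, filtering, search-index navigation), and the plot viewer into
#' `<root>/static/`. All references inside emitted pages are relative; the
#' assets never fetch anything over the network.
#'
#' @param root Bundle root directory.
#' @return Relative paths of the written files, invisibly usable in a
#'   manifest.
#' @export
bundle_assets <- function(root) {
  src_dir <- system.file("runtime", package = "tabreport")
  dir.create(file.path(root, "static"), recursive = TRUE,
             showWarnings = FALSE)
  out <- character(0)
  for (name in runtime_asset_names()) {
    src <- file.path(src_dir, name)
    if (!file.exists(src)) {
      abort(glue("runtime asset '{name}' is missing from the installation"),
            class = "tabreport_io_error")
    }
    dest <- file.path(root, "static", name)
    # byte-exact copy
    writeBin(readBin(src, "raw", file.info(src)$size), dest)
    out <- c(out, file.path("static", name))
  }
  out
}
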