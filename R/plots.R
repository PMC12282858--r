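# ggplot2 methods for the package's result types.

#' Plot a per-column histogram
#'
#' @param object A `report_histogram` from [column_histogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.report_histogram <- function(object, ...) {
  if (attr(object, "kind") == "numeric") {
    df <- tibble(mid = (object$lo + object$hi) / 2,
                 width = object$hi - object$lo,
                 count = object$count)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
      ggplot2::geom_col(width = ifelse(df$width == 0, 1, df$width),
                        fill = "#4682b4") +
      ggplot2::labs(x = "value", y = "count") +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::mutate(as_tibble(object),
                        value = factor(.data$value, levels = .data$value))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$count)) +
      ggplot2::geom_col(fill = "#4682b4") +
      ggplot2::labs(x = NULL, y = "count") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Plot a compression-size summary
#'
#' @param object A `compression_report` from [compression_report()].
#' @param ... Ignored.
#' @return A ggplot comparing byte footprints.
#' @export
autoplot.compression_report <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      serialization = factor(.data$serialization,
                                             levels = .data$serialization))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$serialization,
                                   y = .data$bytes)) +
    ggplot2::geom_col(fill = "#4682b4") +
    ggplot2::labs(x = NULL, y = "bytes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
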