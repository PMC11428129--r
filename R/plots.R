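#' Plot a record table
#'
#' Dot plot of one property across structures, one colour per method, with
#' the two-photon strength drawn on a log10 axis by default (the spread
#' between coupled-cluster and TD-DFT values spans an order of magnitude).
#'
#' @param rs A records tibble.
#' @param property Property column to plot.
#' @param log10_scale Use a log10 y axis.
#' @return A ggplot object.
#' @examples
#' plot_records(builtin_table1())
#' @export
plot_records <- function(rs, property = "delta2pa_au",
                         log10_scale = property %in%
                           c("delta2pa_au", "sigma2pa_GM")) {
  check_property(property)
  df <- tibble::as_tibble(as.data.frame(rs))
  ord <- df |>
    dplyr::filter(.data$method == .data$method[1]) |>
    dplyr::arrange(dplyr::desc(.data[[property]])) |>
    dplyr::pull(.data$structure)
  df$structure <- factor(df$structure, levels = unique(c(ord, df$structure)))
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$structure, y = .data[[property]],
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = property) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (log10_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a benchmark report
#'
#' Bar chart of the per-method MAE for each property, facetted by property
#' on free scales.
#'
#' @param object A `tpa_benchmark` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(build_report(builtin_table1()))
#' @exportS3Method ggplot2::autoplot
autoplot.tpa_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$mae,
    ggplot2::aes(x = .data$method, y = .data$mae, fill = .data$method)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = paste("MAE vs", object$reference),
      title = "Method benchmark: mean absolute errors"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
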