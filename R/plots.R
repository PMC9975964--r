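#' Map a gridded monthly field
#'
#' Tile map of cell concentrations, faceted by representative month when
#' more than one is present.
#'
#' @param field Monthly field or annual surface tibble.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_field <- function(field, title = NULL) {
  p <- ggplot2::ggplot(field, ggplot2::aes(x = .data$col, y = .data$row,
                                           fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(PM[2.5] ~ (mu * g ~ m^-3))) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "column", y = "row") +
    ggplot2::theme_minimal()
  if ("month" %in% names(field) && length(unique(field$month)) > 1) {
    p <- p + ggplot2::facet_wrap(~month)
  }
  p
}

#' @rdname plot_field
#' @param object,x Objects being plotted.
#' @param ... Unused.
#' @export
autoplot.exposure_delta <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$col, y = .data$row,
                                             fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = expression(Delta * PM[2.5]),
                                  low = "darkgreen", mid = "white",
                                  high = "darkorange") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Exposure change: %s vs %s",
                      object$scenario %||% "scenario",
                      object$reference %||% "reference"),
      subtitle = sprintf("population-weighted %+.2f ug m-3 (%+.2f%%)",
                         object$delta_pw, object$pct_change),
      x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @rdname plot_field
#' @export
autoplot.hia_result <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$col, y = .data$row,
                                             fill = .data$deaths)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "deaths", low = "darkgreen",
                                  mid = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s: %+.0f excess deaths", object$erf$label,
                      object$excess_deaths),
      x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Bar chart of excess deaths per scenario and exposure-response function
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_hia_summary <- function(report) {
  stopifnot(inherits(report, "run_report"))
  ggplot2::ggplot(report$hia,
                  ggplot2::aes(x = .data$erf, y = .data$excess_deaths,
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$deaths_lo, ymax = .data$deaths_hi),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::labs(x = NULL, y = "excess deaths vs reference") +
    ggplot2::theme_minimal()
}
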