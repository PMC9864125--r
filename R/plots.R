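# ggplot2 presentation layer.

#' @rdname mc_intake
#' @param object A `canmp_mc` object.
#' @method autoplot canmp_mc
#' @export
autoplot.canmp_mc <- function(object, ...) {
  d <- tibble(intake = object$draws)
  marks <- tibble(
    quantity = factor(c("mean", names(object$percentiles)),
                      levels = c(names(object$percentiles)[1], "mean",
                                 names(object$percentiles)[-1])),
    value = c(object$mean, unname(object$percentiles))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intake)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$value,
                                     linetype = .data$quantity)) +
    ggplot2::labs(x = "Annual intake (items/person/year)", y = "Draws",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a composition summary
#'
#' Horizontal bar chart of percentage shares, faceted by dimension when the
#' input stacks several [composition_summary()] results.
#'
#' @param summary A tibble from [composition_summary()] (or several bound
#'   together).
#' @return A ggplot object.
#' @export
plot_composition <- function(summary) {
  check_df_cols(summary, c("dimension", "label", "share_pct"), "summary")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$share_pct,
                               y = stats::reorder(.data$label, .data$share_pct))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::labs(x = "Share (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an intake table
#'
#' Annual intake against exposure frequency, one line per consumption
#' scenario, for the selected codes (default: the `grand` row).
#'
#' @param intakes A long tibble from [intake_table()].
#' @param codes Codes to display (default `"grand"` if present, else all).
#' @return A ggplot object.
#' @export
plot_intake <- function(intakes, codes = NULL) {
  check_df_cols(intakes, c("code", "label", "exposure_days_per_year",
                           "intake_items_per_year"), "intakes")
  codes <- codes %||%
    (if ("grand" %in% intakes$code) "grand" else unique(intakes$code))
  d <- filter(intakes, .data$code %in% codes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$exposure_days_per_year,
                                  y = .data$intake_items_per_year,
                                  colour = .data$label, group = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~code, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = c(52, 156, 260)) +
    ggplot2::labs(x = "Exposure frequency (days/year)",
                  y = "Annual intake (items/person/year)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot corrected brand concentrations
#'
#' Ranked bar chart of corrected means with standard-error bars.
#'
#' @param concentrations A tibble with `code`, `corrected_mean_per100g` and
#'   optionally `std_error_per100g`.
#' @return A ggplot object.
#' @export
plot_concentrations <- function(concentrations) {
  check_df_cols(concentrations, c("code", "corrected_mean_per100g"),
                "concentrations")
  d <- filter(as_tibble(concentrations), .data$code != "grand")
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$code, .data$corrected_mean_per100g),
    y = .data$corrected_mean_per100g)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Corrected concentration (MPs/100 g)") +
    ggplot2::theme_minimal()
  if ("std_error_per100g" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$corrected_mean_per100g - .data$std_error_per100g,
                   ymax = .data$corrected_mean_per100g + .data$std_error_per100g),
      width = 0.3)
  }
  p
}
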