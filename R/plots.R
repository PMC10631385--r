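#' Plot mortality surfaces, components and forecasts
#'
#' `autoplot()` methods give quick diagnostic graphics: observed log-rate
#' curves coloured by year (the classic rainbow-style functional-data
#' view), estimated eigenfunctions by population, and forecast fans with
#' prediction intervals.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @name wmfpca-plots
NULL

#' Plot observed log-mortality curves by year
#'
#' @param data tidy surface tibble.
#' @return a ggplot object, one panel per population.
#' @export
plot_surface <- function(data) {
  check_surface_df(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$age, .data$log_mx,
                                     group = .data$year, colour = .data$year)) +
    ggplot2::geom_line(alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "age", y = "log death rate", colour = "year")
}

#' @rdname wmfpca-plots
#' @export
autoplot.smooth_curves <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$smoothed,
                                  group = .data$year, colour = .data$year)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "age", y = "smoothed log death rate", colour = "year")
}

#' @rdname wmfpca-plots
#' @export
autoplot.mfpca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$value,
                                  colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "age", y = "eigenfunction")
}

#' @rdname wmfpca-plots
#' @export
autoplot.ufpca <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$term == "eigenfunction")
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "age", y = "eigenfunction")
}

#' @rdname wmfpca-plots
#' @param horizons which forecast horizons to show (default: all).
#' @export
autoplot.mortality_forecast <- function(object, horizons = NULL, ...) {
  d <- tidy(object)
  if (!is.null(horizons)) d <- dplyr::filter(d, .data$horizon %in% horizons)
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$point,
                                  group = .data$year, colour = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$year),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "age", y = "forecast log death rate",
                  colour = "year", fill = "year")
}
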