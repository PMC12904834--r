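#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted pair: measured counts and fitted curves per dose
#'
#' Points are the measured (normalised) counts; lines are the fitted
#' surface evaluated along time at each tested concentration, with the
#' 0 uM control drawn from the no-drug growth curve.
#'
#' @param object A `dtr_fit` object.
#' @param n_time Number of time points for the fitted curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dtr_fit <- function(object, n_time = 200, ...) {
  obs <- object$data$counts
  tt <- seq(object$data$t_min, object$data$t_max, length.out = n_time)
  curves <- tidyr::expand_grid(concentration_uM = object$data$doses, time_h = tt)
  curves$count <- model_counts(object$params, curves$concentration_uM,
                               curves$time_h)
  dose_lab <- function(x) factor(ifelse(x == 0, "0 (control)", format(x)),
                                 levels = c("0 (control)",
                                            format(sort(unique(x[x > 0])))))
  obs$dose <- dose_lab(obs$concentration_uM)
  curves$dose <- dose_lab(curves$concentration_uM)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h, y = .data$count,
                                    colour = .data$dose)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "time (h)", y = "normalised cell count",
                  colour = "dose (uM)",
                  title = paste(stats::na.omit(c(object$data$cell_line,
                                                 object$data$drug)),
                                collapse = " / ")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a dose-time-response surface
#'
#' @param params A [dtr_params] object.
#' @param domain An [integration_domain] giving the plotted rectangle.
#' @param rescaled Plot the growth-rate-rescaled surface `f'` instead of
#'   `f` (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_surface <- function(params, domain, rescaled = FALSE) {
  params <- as_dtr_params(params)
  dd <- seq(domain$d_min, domain$d_max, length.out = domain$n_dose + 1)
  tt <- seq(domain$t_min, domain$t_max, length.out = domain$n_time + 1)
  grid <- tidyr::expand_grid(d = dd, t = tt)
  grid$f <- if (rescaled) gr_surface(grid$d, grid$t, params)
            else dtr_surface(grid$d, grid$t, params)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$d,
                                     fill = .data$f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "count (fold)") +
    ggplot2::labs(x = "time (h)", y = "log10 concentration (uM)") +
    ggplot2::theme_minimal()
}
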