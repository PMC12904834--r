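#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted dose-time-response surface
#'
#' @param x A `dtr_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.dtr_fit <- function(x, ...) {
  tibble::tibble(term = param_names(),
                 estimate = unname(unlist(x$params[param_names()])))
}

#' One-row fit summary
#'
#' @param x A `dtr_fit` object.
#' @param ... Unused.
#' @return Tibble with fit diagnostics: `mape_percent`, `n_points`,
#'   `converged`, `objective_value`, `start_index`.
#' @exportS3Method generics::glance
glance.dtr_fit <- function(x, ...) {
  tibble::tibble(mape_percent = x$mape_percent, n_points = x$n_points,
                 converged = x$converged, objective_value = x$objective_value,
                 start_index = x$start_index)
}

#' Measurements with fitted values and relative residuals
#'
#' @param x A `dtr_fit` object.
#' @param data Measurement tibble; defaults to the fitted data.
#' @param ... Unused.
#' @return `data` with `.fitted` (model count) and `.resid`
#'   (relative error `(A - F)/A`) appended.
#' @exportS3Method generics::augment
augment.dtr_fit <- function(x, data = NULL, ...) {
  data <- data %||% x$data$counts
  data$.fitted <- model_counts(x$params, data$concentration_uM, data$time_h)
  data$.resid <- (data$count - data$.fitted) / data$count
  data
}

#' @exportS3Method generics::tidy
tidy.grivus_result <- function(x, ...) {
  tibble::tibble(volume_raw = x$volume_raw, volume_upper = x$volume_upper,
                 volume_lower = x$volume_lower,
                 volume_unaffected = x$volume_unaffected,
                 grivus_normalized = x$grivus_normalized)
}

#' @exportS3Method generics::tidy
tidy.concordance <- function(x, ...) {
  tibble::tibble(ccc = x$ccc, pcc = x$pcc, ci_low = x$ci_low,
                 ci_high = x$ci_high, n = x$n, n_boot = x$n_boot,
                 level = x$level)
}
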