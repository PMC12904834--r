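#' Dose-time-response surface parameters
#'
#' Bundles the six parameters of the dose-time-response surface into a
#' validated `dtr_params` object. The surface combines a 4-parameter
#' logistic dose-response curve with logistic growth in time: the upper
#' asymptote of the dose-response curve at time `t` is the untreated
#' growth curve `alpha(t)` and the lower asymptote is the
#' infinite-dose growth curve `delta(t)`.
#'
#' Both growth curves have the form `a * 2^(k*t) / ((a - 1) + 2^(k*t))`,
#' which starts at exactly 1 at `t = 0` (counts are normalised to the
#' initial count) and plateaus at `a`. The denominator has a pole at
#' finite positive `t` when `a < 1` and `k < 0`; such combinations are
#' rejected so that the curve is defined on all of `t >= 0`.
#'
#' @param k_alpha Growth rate of untreated cells (1/h). May be negative
#'   for dying cultures.
#' @param a_alpha Plateau of untreated growth, as fold of the initial
#'   count. Must be positive, and at least 1 when `k_alpha < 0`.
#' @param k_delta Growth rate under infinitely high dose (1/h).
#' @param a_delta Plateau under infinitely high dose, fold of initial
#'   count. Must be positive, and at least 1 when `k_delta < 0`.
#' @param k_beta Steepness scaling factor of the dose-response transition
#'   (dimensionless, `>= 0`). The effective Hill-type slope at time `t`
#'   is `k_beta * |alpha(t) - delta(t)|`.
#' @param k_gamma `log10` of the midpoint concentration (IC50 for
#'   inhibitors, EC50 for growth stimulators), with concentration in uM.
#'
#' @return An object of class `dtr_params`: a named list with the six
#'   parameters.
#' @examples
#' p <- dtr_params(k_alpha = 0.05, a_alpha = 10, k_delta = 0.01,
#'                 a_delta = 2, k_beta = 1, k_gamma = 0)
#' dtr_surface(d = 0, t = 24, params = p)
#' @export
dtr_params <- function(k_alpha, a_alpha, k_delta, a_delta, k_beta, k_gamma) {
  vals <- c(k_alpha = k_alpha, a_alpha = a_alpha, k_delta = k_delta,
            a_delta = a_delta, k_beta = k_beta, k_gamma = k_gamma)
  if (!is.numeric(vals) || length(vals) != 6L) {
    stop("all six parameters must be numeric scalars", call. = FALSE)
  }
  if (any(!is.finite(vals))) {
    stop("parameters must be finite; got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (a_alpha <= 0) stop("a_alpha must be positive", call. = FALSE)
  if (a_delta <= 0) stop("a_delta must be positive", call. = FALSE)
  if (k_beta < 0) stop("k_beta must be >= 0", call. = FALSE)
  if (a_alpha < 1 && k_alpha < 0) {
    stop("a_alpha < 1 with k_alpha < 0 places a pole of alpha(t) at finite t; ",
         "use a_alpha >= 1 for shrinking cultures", call. = FALSE)
  }
  if (a_delta < 1 && k_delta < 0) {
    stop("a_delta < 1 with k_delta < 0 places a pole of delta(t) at finite t; ",
         "use a_delta >= 1 for shrinking cultures", call. = FALSE)
  }
  new_dtr_params(k_alpha, a_alpha, k_delta, a_delta, k_beta, k_gamma)
}

# unvalidated constructor for hot paths (optimiser keeps values in bounds)
new_dtr_params <- function(k_alpha, a_alpha, k_delta, a_delta, k_beta, k_gamma) {
  structure(
    list(k_alpha = k_alpha, a_alpha = a_alpha, k_delta = k_delta,
         a_delta = a_delta, k_beta = k_beta, k_gamma = k_gamma),
    class = "dtr_params"
  )
}

#' Coerce a named vector or list to `dtr_params`
#'
#' @param x Named numeric vector or list containing `k_alpha`, `a_alpha`,
#'   `k_delta`, `a_delta`, `k_beta`, `k_gamma`.
#' @return A validated [dtr_params] object.
#' @export
as_dtr_params <- function(x) {
  if (inherits(x, "dtr_params")) return(x)
  x <- as.list(x)
  need <- param_names()
  if (!all(need %in% names(x))) {
    stop("missing parameter(s): ", paste(setdiff(need, names(x)), collapse = ", "),
         call. = FALSE)
  }
  do.call(dtr_params, lapply(x[need], as.numeric))
}

param_names <- function() {
  c("k_alpha", "a_alpha", "k_delta", "a_delta", "k_beta", "k_gamma")
}

#' @export
print.dtr_params <- function(x, ...) {
  cat("<dtr_params>\n")
  cat(sprintf("  growth   : k_alpha = %.4g /h, plateau a_alpha = %.4g\n",
              x$k_alpha, x$a_alpha))
  cat(sprintf("  inf dose : k_delta = %.4g /h, plateau a_delta = %.4g\n",
              x$k_delta, x$a_delta))
  cat(sprintf("  potency  : k_gamma = %.4g (IC50 = %.4g uM), steepness k_beta = %.4g\n",
              x$k_gamma, 10^x$k_gamma, x$k_beta))
  invisible(x)
}

#' @export
as.double.dtr_params <- function(x, ...) {
  unlist(x[param_names()])
}
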