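#' @title Dose-time-response surface evaluation
#' @description Pure evaluation of the surface `f(d, t)`, its time-dependent
#'   parameter curves, and the growth-rate-rescaled surface used by GRIVUS.
#' @name dtr-model
NULL

# exponents of 2 and 10 are clamped so that the logistic ratio saturates
# instead of overflowing (relevant once the rescaled exponent is 1 per hour)
clamp_exponent <- function(x) pmin(pmax(x, -300), 300)

logistic_growth <- function(t, k, a, label = "growth") {
  if (any(t < 0, na.rm = TRUE)) {
    stop(label, "(t): t must be >= 0", call. = FALSE)
  }
  pow <- 2^clamp_exponent(k * t)
  den <- (a - 1) + pow
  bad <- is.finite(den) & den <= 0
  if (any(bad)) {
    stop(sprintf("%s(t): pole in logistic growth at t = %g ((a-1) + 2^(k*t) <= 0)",
                 label, t[bad][1]), call. = FALSE)
  }
  a * pow / den
}

#' Untreated growth curve alpha(t)
#'
#' Cell count (fold of initial) at time `t` in the absence of drug:
#' `alpha(t) = a_alpha * 2^(k_alpha*t) / ((a_alpha - 1) + 2^(k_alpha*t))`.
#' `alpha(0) = 1` exactly and, for `k_alpha > 0`, `alpha(t) -> a_alpha`
#' as `t -> Inf`.
#'
#' @param t Time in hours (vectorised, `>= 0`).
#' @param params A [dtr_params] object.
#' @return Numeric vector of fold-of-initial counts.
#' @export
growth_alpha <- function(t, params) {
  logistic_growth(t, params$k_alpha, params$a_alpha, "alpha")
}

#' Infinite-dose growth curve delta(t)
#'
#' Cell count (fold of initial) at time `t` under an infinitely high
#' dose; same logistic form as [growth_alpha()] with `(k_delta, a_delta)`.
#'
#' @inheritParams growth_alpha
#' @return Numeric vector of fold-of-initial counts.
#' @export
growth_delta <- function(t, params) {
  logistic_growth(t, params$k_delta, params$a_delta, "delta")
}

#' Time-dependent steepness beta(t)
#'
#' `beta(t) = k_beta * |alpha(t) - delta(t)|`: the dose-response
#' transition is steepest where control and infinite-dose counts are
#' furthest apart, and flat (`beta = 0`) at `t = 0` where both equal 1.
#'
#' @inheritParams growth_alpha
#' @return Numeric vector, `>= 0`.
#' @export
steepness_beta <- function(t, params) {
  params$k_beta * abs(growth_alpha(t, params) - growth_delta(t, params))
}

#' Evaluate the dose-time-response surface
#'
#' `f(d, t) = (alpha(t) - delta(t)) / (1 + 10^(beta(t) * (d - k_gamma))) + delta(t)`,
#' a 4-parameter logistic in log10 dose whose asymptotes move in time along
#' the two growth curves. The vehicle control (0 uM) corresponds to the
#' limit `d -> -Inf`, which evaluates to `alpha(t)`; `d = Inf` gives
#' `delta(t)`. At `t = 0` the surface is identically 1 for every dose.
#'
#' @param d `log10` concentration in uM (vectorised; `-Inf` and `Inf`
#'   are accepted as the no-drug and saturating-dose limits).
#' @param t Time in hours (vectorised, recycled against `d`).
#' @param params A [dtr_params] object.
#' @return Numeric vector of fold-of-initial counts.
#' @examples
#' p <- dtr_params(0.05, 10, 0.01, 2, 1, 0)
#' dtr_surface(d = -Inf, t = 24, params = p)  # control: alpha(24)
#' dtr_surface(d = 0, t = 24, params = p)     # at the IC50: (alpha+delta)/2
#' @export
dtr_surface <- function(d, t, params) {
  n <- max(length(d), length(t))
  d <- rep_len(d, n)
  t <- rep_len(t, n)
  al <- growth_alpha(t, params)
  de <- growth_delta(t, params)
  be <- params$k_beta * abs(al - de)
  e <- be * (d - params$k_gamma)
  # beta = 0 flattens the curve: the d -> +/-Inf limits coincide with the
  # midpoint value, so the 0 * Inf indeterminate form resolves to 0
  e[be == 0] <- 0
  (al - de) / (1 + 10^clamp_exponent(e)) + de
}

#' Growth-rate rescaling of the exponential prefactors
#'
#' Expresses both growth rates as a ratio to the larger of the two, so
#' the exponential prefactors of `t` stay at or below 1: divide by
#' `k_alpha` when `k_alpha >= k_delta`, else by `k_delta`. When both
#' rates are non-positive (a dying control, not covered by the usual
#' rule) the magnitudes are scaled by `max(|k_alpha|, |k_delta|)` with
#' signs preserved; if both are exactly zero the rates are returned
#' unchanged.
#'
#' @param params A [dtr_params] object.
#' @return Named numeric vector `c(k_alpha = ..., k_delta = ...)` of
#'   scaled (dimensionless) rates, both `<= 1`.
#' @export
gr_scaled_rates <- function(params) {
  ka <- params$k_alpha
  kd <- params$k_delta
  s <- max(ka, kd)
  if (s <= 0) s <- max(abs(ka), abs(kd))
  if (s == 0) return(c(k_alpha = ka, k_delta = kd))
  c(k_alpha = ka / s, k_delta = kd / s)
}

#' Parameters of the growth-rate-rescaled surface
#'
#' Returns the input parameters with `(k_alpha, k_delta)` replaced by
#' their [gr_scaled_rates()] values; plateaus, steepness factor and
#' potency are untouched.
#'
#' @inheritParams gr_scaled_rates
#' @return A `dtr_params` object with rescaled growth rates.
#' @export
gr_params <- function(params) {
  r <- gr_scaled_rates(params)
  new_dtr_params(r[["k_alpha"]], params$a_alpha, r[["k_delta"]],
                 params$a_delta, params$k_beta, params$k_gamma)
}

#' Growth-rate-rescaled surface f'(d, t)
#'
#' The surface used for GRIVUS: identical in form to [dtr_surface()] but
#' built from the rescaled growth curves `alpha'(t)`, `delta'(t)` and
#' the corresponding steepness `beta'(t) = k_beta * |alpha'(t) - delta'(t)|`.
#' Invariant under joint positive rescaling of the two growth rates, so
#' fast- and slow-dividing lines with the same relative drug effect score
#' alike.
#'
#' @inheritParams dtr_surface
#' @return Numeric vector of fold-of-initial counts.
#' @export
gr_surface <- function(d, t, params) {
  dtr_surface(d, t, gr_params(params))
}
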