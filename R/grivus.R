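#' Integration domain for volume-under-surface calculations
#'
#' Defines the rectangle in (log10 dose, time) over which the volume
#' under a dose-time-response surface is approximated, together with the
#' grid resolution. The default grid of 100 x 100 cells gives 10 000
#' cuboids.
#'
#' @param d_min,d_max Dose-axis limits, log10 concentration in uM.
#' @param t_min,t_max Time-axis limits in hours.
#' @param n_dose,n_time Number of grid cells (cuboids) along each axis.
#' @return An `integration_domain` object.
#' @export
integration_domain <- function(d_min, d_max, t_min = 0, t_max = 120,
                               n_dose = 100, n_time = 100) {
  stopifnot(is.finite(d_min), is.finite(d_max), is.finite(t_min),
            is.finite(t_max))
  if (d_min >= d_max) stop("d_min must be < d_max", call. = FALSE)
  if (t_min >= t_max) stop("t_min must be < t_max", call. = FALSE)
  if (n_dose < 1 || n_time < 1) stop("need at least one cell per axis", call. = FALSE)
  structure(
    list(d_min = d_min, d_max = d_max, t_min = t_min, t_max = t_max,
         n_dose = as.integer(n_dose), n_time = as.integer(n_time)),
    class = "integration_domain"
  )
}

#' @export
print.integration_domain <- function(x, ...) {
  cat(sprintf("<integration_domain> d in [%.4g, %.4g] log10(uM), t in [%g, %g] h, %d x %d cells\n",
              x$d_min, x$d_max, x$t_min, x$t_max, x$n_dose, x$n_time))
  invisible(x)
}

#' Dose-axis limits from tested concentration levels
#'
#' The natural dose domain for the volume: from the lowest non-zero
#' tested concentration to the highest, on the log10 scale. The 0 uM
#' vehicle control has no log-dose coordinate and enters the model only
#' through the control growth curve.
#'
#' @param doses Tested concentrations in uM (may include 0).
#' @return Length-2 numeric vector `c(d_min, d_max)` in log10(uM).
#' @export
dose_domain <- function(doses) {
  nz <- unique(doses[is.finite(doses) & doses > 0])
  if (length(nz) < 2) {
    stop("need at least two distinct non-zero concentrations", call. = FALSE)
  }
  c(log10(min(nz)), log10(max(nz)))
}

# corner values on the (n_dose+1) x (n_time+1) node grid and both cuboid sums
riemann_volumes <- function(g, domain) {
  dd <- seq(domain$d_min, domain$d_max, length.out = domain$n_dose + 1L)
  tt <- seq(domain$t_min, domain$t_max, length.out = domain$n_time + 1L)
  G <- outer(dd, tt, g)
  if (any(!is.finite(G))) {
    idx <- which(!is.finite(G), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite surface value at grid node d = %g, t = %g",
                 dd[idx[1L]], tt[idx[2L]]), call. = FALSE)
  }
  nd <- domain$n_dose
  nt <- domain$n_time
  c00 <- G[seq_len(nd), seq_len(nt), drop = FALSE]
  c10 <- G[seq_len(nd) + 1L, seq_len(nt), drop = FALSE]
  c01 <- G[seq_len(nd), seq_len(nt) + 1L, drop = FALSE]
  c11 <- G[seq_len(nd) + 1L, seq_len(nt) + 1L, drop = FALSE]
  cell_area <- (dd[2L] - dd[1L]) * (tt[2L] - tt[1L])
  upper <- sum(pmax(c00, c10, c01, c11)) * cell_area
  lower <- sum(pmin(c00, c10, c01, c11)) * cell_area
  list(upper = upper, lower = lower, average = (upper + lower) / 2)
}

#' Cuboid (Riemann) approximation of the volume under a surface
#'
#' Approximates the integral of `g(d, t)` over the domain with one
#' cuboid per grid cell. The cuboid height is the maximum (`upper`) or
#' minimum (`lower`) of the surface at the four cell corners; `average`
#' is the mean of the two sums and is exact for surfaces that are linear
#' along each axis. For surfaces monotone in each coordinate on the
#' domain the true integral is bracketed by `[lower, upper]`.
#'
#' @param g Function of `(d, t)`, vectorised in both arguments.
#' @param domain An [integration_domain].
#' @param mode One of `"average"` (default), `"upper"`, `"lower"`.
#' @return The approximate volume (units of `g` times log10(uM) times hours).
#' @examples
#' dom <- integration_domain(-2, 1, 0, 120, 50, 50)
#' riemann_volume(function(d, t) rep(1, length(d)), dom)  # area = 3 * 120
#' @export
riemann_volume <- function(g, domain, mode = c("average", "upper", "lower")) {
  mode <- match.arg(mode)
  riemann_volumes(g, domain)[[mode]]
}

#' GRIVUS: growth-rate-normalised volume under the surface
#'
#' Computes the volume under the growth-rate-rescaled surface `f'(d, t)`
#' (averaged upper/lower cuboid approximation) and normalises it by the
#' "unaffected" volume -- the volume the surface would enclose if every
#' dose grew like the untreated control, i.e. the volume of the
#' dose-constant surface `alpha'(t)` on the same domain and grid. For an
#' inhibitory drug the normalised value lies in (0, 1], with 1 meaning
#' no drug effect anywhere on the domain.
#'
#' @param params A [dtr_params] object.
#' @param domain An [integration_domain]; typically built with
#'   [dose_domain()] limits and the experiment's time window.
#' @return A `grivus_result` with fields `volume_raw`, `volume_upper`,
#'   `volume_lower`, `volume_unaffected`, `grivus_normalized`, `domain`.
#' @examples
#' p <- dtr_params(0.05, 10, 0.01, 2, 1, 0)
#' dom <- integration_domain(log10(0.016), 1, 0, 120)
#' grivus(p, dom)
#' @export
grivus <- function(params, domain) {
  params <- as_dtr_params(params)
  stopifnot(inherits(domain, "integration_domain"))
  gp <- gr_params(params)
  vol <- riemann_volumes(function(d, t) dtr_surface(d, t, gp), domain)
  unaff <- riemann_volumes(function(d, t) growth_alpha(t, gp), domain)$average
  if (!is.finite(unaff) || unaff <= 0) {
    stop("unaffected volume is not positive; control growth curve is pathological",
         call. = FALSE)
  }
  structure(
    list(volume_raw = vol$average,
         volume_upper = vol$upper,
         volume_lower = vol$lower,
         volume_unaffected = unaff,
         grivus_normalized = vol$average / unaff,
         domain = domain),
    class = "grivus_result"
  )
}

#' @export
print.grivus_result <- function(x, ...) {
  cat("<grivus_result>\n")
  cat(sprintf("  volume (avg of upper/lower cuboids): %.6g  [%.6g, %.6g]\n",
              x$volume_raw, x$volume_lower, x$volume_upper))
  cat(sprintf("  unaffected volume: %.6g\n", x$volume_unaffected))
  cat(sprintf("  normalised GRIVUS: %.6g\n", x$grivus_normalized))
  invisible(x)
}

#' GRIVUS scores for a table of fitted surfaces
#'
#' Data-frame-first wrapper: takes the output of [fit_dose_time()] (one
#' row per cell line-drug pair with a `fit` list-column) and appends the
#' volume and normalised GRIVUS of each fitted surface. The dose domain
#' defaults to the tested concentration range of each pair and the time
#' window to `[0, t_max]`.
#'
#' @param fits Tibble from [fit_dose_time()].
#' @param t_max End of the time window in hours; default is each pair's
#'   last measured time.
#' @param n_dose,n_time Grid resolution (default 100 x 100 = 10 000 cuboids).
#' @return The input tibble with columns `volume_raw`,
#'   `volume_unaffected`, `grivus_normalized` and a `grivus` list-column.
#' @export
grivus_scores <- function(fits, t_max = NULL, n_dose = 100, n_time = 100) {
  stopifnot(is.data.frame(fits), "fit" %in% names(fits))
  res <- purrr::map(fits$fit, function(f) {
    dom <- fit_domain(f, t_max = t_max, n_dose = n_dose, n_time = n_time)
    grivus(f$params, dom)
  })
  fits$volume_raw <- purrr::map_dbl(res, "volume_raw")
  fits$volume_unaffected <- purrr::map_dbl(res, "volume_unaffected")
  fits$grivus_normalized <- purrr::map_dbl(res, "grivus_normalized")
  fits$grivus <- res
  fits
}

# default integration domain for one fitted pair
fit_domain <- function(fit, t_max = NULL, n_dose = 100, n_time = 100) {
  dd <- dose_domain(fit$data$doses)
  integration_domain(dd[1], dd[2], t_min = 0,
                     t_max = t_max %||% fit$data$t_max,
                     n_dose = n_dose, n_time = n_time)
}
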