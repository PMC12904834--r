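#' Mean absolute percentage error
#'
#' `MAPE = 100/n * sum(|(A - F) / A|)` between actual values `A` and
#' forecast (model) values `F`. Scale-invariant: rescaling both series
#' by the same non-zero factor leaves it unchanged.
#'
#' @param actual Measured values; must all be non-zero.
#' @param forecast Model values, same length.
#' @return MAPE in percent (`>= 0`; 0 iff the sequences are identical).
#' @examples
#' mape(c(1, 2), c(1.1, 1.8))  # 10
#' @export
mape <- function(actual, forecast) {
  if (length(actual) != length(forecast)) {
    stop("actual and forecast must have the same length", call. = FALSE)
  }
  if (length(actual) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(actual)) || any(!is.finite(forecast))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(actual == 0)) {
    stop("actual values must be non-zero (relative error undefined at 0)",
         call. = FALSE)
  }
  100 * mean(abs((actual - forecast) / actual))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 * PCC * sx * sy / (sx^2 + sy^2 + (mx - my)^2)`, measuring
#' agreement with the identity line rather than mere correlation: a
#' perfectly correlated pair with a shift or a slope other than 1 has
#' `|CCC| < |PCC|`. Population (1/n) variances by default, per Lin's
#' original definition.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`, each with
#'   non-zero variance.
#' @param variance `"population"` (1/n, default) or `"sample"` (1/(n-1));
#'   the point estimate is identical whenever both series use the same
#'   divisor except through the mean-shift term.
#' @return CCC in `[-1, 1]`.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
ccc <- function(x, y, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  if (variance == "population") {
    sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  } else {
    sx2 <- stats::var(x); sy2 <- stats::var(y)
  }
  if (sx2 == 0 || sy2 == 0) {
    stop("zero variance: CCC undefined", call. = FALSE)
  }
  pcc <- stats::cor(x, y)
  2 * pcc * sqrt(sx2) * sqrt(sy2) / (sx2 + sy2 + (mx - my)^2)
}

#' Concordance with a percentile bootstrap confidence interval
#'
#' Point estimates of CCC and Pearson correlation plus a percentile
#' bootstrap interval for the CCC from paired resampling of index pairs
#' with replacement (default 100 repetitions, 95% level). A bootstrap
#' replicate in which either resampled series is constant is redrawn (up
#' to 100 retries per replicate) and counted in `n_degenerate` if it
#' never succeeds.
#'
#' @inheritParams ccc
#' @param n_boot Number of bootstrap repetitions (default 100).
#' @param level Coverage probability of the interval (default 0.95).
#' @param seed Optional integer seed; with a seed the result is fully
#'   deterministic and the caller's RNG state is left untouched.
#' @return A `concordance` object with fields `ccc`, `pcc`, `ci_low`,
#'   `ci_high`, `n_boot`, `level`, `n`, `n_degenerate`.
#' @export
concordance <- function(x, y, n_boot = 100, level = 0.95, seed = NULL,
                        variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  point <- ccc(x, y, variance = variance)
  pcc <- stats::cor(x, y)
  n <- length(x)

  draw <- function() {
    reps <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        if (stats::sd(xb) > 0 && stats::sd(yb) > 0) {
          reps[b] <- ccc(xb, yb, variance = variance)
          break
        }
      }
    }
    reps
  }
  reps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_degenerate <- sum(is.na(reps))
  if (n_degenerate == n_boot) {
    stop("all bootstrap replicates degenerate (constant resamples)", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- stats::quantile(reps, probs = probs, na.rm = TRUE, names = FALSE)
  structure(
    list(ccc = point, pcc = pcc, ci_low = qs[1], ci_high = qs[2],
         n_boot = n_boot, level = level, n = n, n_degenerate = n_degenerate),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("CCC = %.4f [%g%% CI %.4f, %.4f], PCC = %.4f (n = %d, %d bootstrap reps)\n",
              x$ccc, 100 * x$level, x$ci_low, x$ci_high, x$pcc, x$n, x$n_boot))
  invisible(x)
}
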