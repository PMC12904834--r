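test_that("growth curves reproduce hand-computed values and start at 1", {
  expect_equal(growth_alpha(0, p_ref), 1)
  expect_equal(growth_delta(0, p_ref), 1)
  # frozen values from direct evaluation of the logistic formula
  expect_equal(growth_alpha(24, p_ref), 2.0335629251, tolerance = 1e-9)
  expect_equal(growth_delta(24, p_ref), 1.0829863688, tolerance = 1e-9)
  p_neg <- dtr_params(-0.05, 10, 0.01, 2, 1, 0)
  expect_equal(growth_alpha(24, p_neg), 0.4613275910, tolerance = 1e-9)
  # zero growth rate pins the curve at 1 for all t
  p_flat <- dtr_params(0.05, 10, 0, 7, 1, 0)
  expect_equal(growth_delta(c(0, 17, 120), p_flat), c(1, 1, 1))
  # plateau reached as t -> Inf for positive rate
  expect_equal(growth_alpha(1e5, p_ref), 10, tolerance = 1e-8)
  # cross-check against the independent plain-formula oracle on a grid
  tt <- seq(0, 120, by = 7.5)
  expect_equal(growth_alpha(tt, p_ref), ref_growth(tt, 0.05, 10), tolerance = 1e-12)
})

test_that("steepness is k_beta * |alpha - delta| and vanishes at t = 0", {
  expect_equal(steepness_beta(0, p_ref), 0)
  expect_equal(steepness_beta(24, p_ref), 0.9505765563, tolerance = 1e-9)
  p0 <- dtr_params(0.05, 10, 0.01, 2, 0, 0)
  expect_equal(steepness_beta(c(0, 24, 120), p0), c(0, 0, 0))
  expect_true(all(steepness_beta(seq(0, 120, 3), p_ref) >= 0))
})

test_that("surface midpoint, asymptotes, and t = 0 plane are exact", {
  # midpoint at d = k_gamma is the mean of the two growth curves
  expect_equal(dtr_surface(0, 24, p_ref), 1.5582746470, tolerance = 1e-9)
  expect_equal(dtr_surface(1, 24, p_ref), 1.1787686247, tolerance = 1e-9)
  # the t = 0 plane is identically 1 for any dose, including the limits
  expect_equal(dtr_surface(c(-Inf, -3, 0, 5, Inf), 0, p_ref), rep(1, 5))
  # symbolic dose limits evaluate the two growth curves exactly
  expect_identical(dtr_surface(-Inf, 24, p_ref), growth_alpha(24, p_ref))
  expect_identical(dtr_surface(Inf, 24, p_ref), growth_delta(24, p_ref))
})

test_that("parameter validation rejects poles and bad domains", {
  expect_error(dtr_params(0.05, -1, 0.01, 2, 1, 0), "a_alpha")
  expect_error(dtr_params(0.05, 10, 0.01, 2, -0.5, 0), "k_beta")
  # a < 1 with negative rate puts a pole at finite positive t
  expect_error(dtr_params(-0.05, 0.5, 0.01, 2, 1, 0), "pole")
  expect_error(dtr_params(0.05, 10, -0.01, 0.9, 1, 0), "pole")
  expect_error(dtr_params(NA, 10, 0.01, 2, 1, 0), "finite")
  # a in (0, 1) is fine when the paired rate is non-negative
  expect_silent(dtr_params(0.05, 10, 0.02, 0.4, 1, 0))
  # evaluation-time pole detection names the offending t
  p_bad <- structure(
    list(k_alpha = -0.05, a_alpha = 0.5, k_delta = 0.01, a_delta = 2,
         k_beta = 1, k_gamma = 0), class = "dtr_params")
  expect_error(growth_alpha(100, p_bad), "pole.*t = 100")
  expect_error(growth_alpha(-1, p_ref), "t must be >= 0")
})

test_that("surface identities hold over random parameter draws", {
  withr::local_seed(101)
  for (i in 1:200) {
    p <- rand_params()
    tt <- c(0, 3, 11, 24, 48, 120)
    # t = 0 plane
    expect_equal(dtr_surface(runif(3, -3, 3), 0, p), rep(1, 3))
    # midpoint identity at every time
    expect_equal(dtr_surface(p$k_gamma, tt, p),
                 (growth_alpha(tt, p) + growth_delta(tt, p)) / 2,
                 tolerance = 1e-12)
    # monotone in dose, direction set by sign(alpha - delta)
    t1 <- 48
    dgrid <- seq(p$k_gamma - 4, p$k_gamma + 4, length.out = 25)
    fd <- dtr_surface(dgrid, t1, p)
    gap <- growth_alpha(t1, p) - growth_delta(t1, p)
    if (gap >= 0) expect_true(all(diff(fd) <= 1e-12)) else
      expect_true(all(diff(fd) >= -1e-12))
    # tail deviation bounded by the analytic tail of the logistic
    be <- steepness_beta(t1, p)
    expect_lte(abs(dtr_surface(p$k_gamma - 10, t1, p) - growth_alpha(t1, p)),
               abs(gap) * 10^(-10 * be) + 1e-12)
    expect_lte(abs(dtr_surface(p$k_gamma + 10, t1, p) - growth_delta(t1, p)),
               abs(gap) * 10^(-10 * be) + 1e-12)
  }
})

test_that("growth-rate rescaling follows the larger-rate rule", {
  expect_equal(gr_scaled_rates(dtr_params(0.05, 10, 0.01, 2, 1, 0)),
               c(k_alpha = 1, k_delta = 0.2))
  # when the treated culture outgrows the control, divide by k_delta
  expect_equal(gr_scaled_rates(dtr_params(0.01, 10, 0.05, 2, 1, 0)),
               c(k_alpha = 0.2, k_delta = 1))
  # joint positive rescaling cancels
  for (c_mult in c(0.2, 3, 17)) {
    expect_equal(gr_scaled_rates(dtr_params(c_mult * 0.05, 10, c_mult * 0.01, 2, 1, 0)),
                 c(k_alpha = 1, k_delta = 0.2), tolerance = 1e-14)
  }
  # dying culture: both rates non-positive, scale by largest magnitude,
  # signs preserved so the prefactors stay bounded by 1 in magnitude
  expect_equal(gr_scaled_rates(dtr_params(-0.04, 10, -0.01, 2, 1, 0)),
               c(k_alpha = -1, k_delta = -0.25))
  # both exactly zero: rescaled surface is the original surface
  p0 <- dtr_params(0, 10, 0, 2, 1, 0)
  expect_equal(gr_scaled_rates(p0), c(k_alpha = 0, k_delta = 0))
  d <- seq(-2, 1, 0.5)
  expect_identical(gr_surface(d, 48, p0), dtr_surface(d, 48, p0))
})

test_that("rescaled surface matches hand-computed value and is rate-scale invariant", {
  # delta'(24) with scaled exponent 0.01/0.05 = 0.2
  expect_equal(gr_surface(Inf, 24, p_ref), 1.9306942105, tolerance = 1e-9)
  expect_equal(gr_surface(Inf, 24, p_ref), ref_growth(24, 0.2, 2), tolerance = 1e-12)
  # no-effect parameters: f' is the control curve for every dose
  p_eq <- dtr_params(0.03, 6, 0.03, 6, 1.4, -0.5)
  tt <- c(0, 24, 96)
  for (d in c(-Inf, -2, 0, 1, Inf)) {
    expect_equal(gr_surface(d, tt, p_eq), growth_alpha(tt, gr_params(p_eq)),
                 tolerance = 1e-14)
  }
  # doubling both growth rates changes nothing
  withr::local_seed(7)
  for (i in 1:20) {
    p <- rand_params()
    p2 <- dtr_params(2 * p$k_alpha, p$a_alpha, 2 * p$k_delta, p$a_delta,
                     p$k_beta, p$k_gamma)
    d <- runif(5, -2, 1.5); t <- runif(5, 0, 120)
    expect_equal(gr_surface(d, t, p2), gr_surface(d, t, p), tolerance = 1e-12)
  }
  # rescaling keeps exponential prefactors at or below 1 even at long times
  expect_true(is.finite(gr_surface(0, 2000, p_ref)))
})
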