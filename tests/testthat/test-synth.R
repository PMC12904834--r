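test_that("plate layout matches the emulated experiment", {
  spec <- synthetic_spec()
  expect_equal(spec$doses, c(0, 0.016, 0.08, 0.4, 2, 10))
  expect_equal(range(spec$times), c(0, 120))
  expect_equal(unique(diff(spec$times)), 3)
  sim <- simulate_counts(p_ref, spec, seed = 4)
  expect_equal(nrow(sim$counts), 6 * 41 * 3)
  # untreated doubling-time range 20-40 h maps to k_alpha in [1/40, 1/20]
  expect_equal(1 / spec$ranges$k_alpha, c(40, 20))
  expect_error(synthetic_spec(doses = c(0.1, 1)), "vehicle control")
  expect_error(synthetic_spec(noise_cv = -1), "noise_cv")
})

test_that("parameter draws respect ranges and model validity", {
  spec <- synthetic_spec()
  withr::with_seed(9, {
    for (i in 1:200) {
      p <- sample_params(spec)
      for (nm in names(spec$ranges)) {
        expect_gte(p[[nm]], spec$ranges[[nm]][1])
        expect_lte(p[[nm]], spec$ranges[[nm]][2])
      }
    }
  })
  # degenerate ranges pin the draw exactly
  spec_fix <- synthetic_spec(ranges = lapply(unclass(p_ref), function(v) c(v, v)))
  p <- withr::with_seed(1, sample_params(spec_fix))
  expect_equal(unlist(p), unlist(p_ref))
})

test_that("noise-free counts equal the model and seeds reproduce exactly", {
  spec0 <- synthetic_spec(noise_cv = 0)
  sim <- simulate_counts(p_ref, spec0, seed = 12)
  expect_equal(sim$counts$count,
               grivus:::model_counts(p_ref, sim$counts$concentration_uM,
                                     sim$counts$time_h),
               tolerance = 1e-12)
  spec <- synthetic_spec()
  s1 <- simulate_counts(p_ref, spec, seed = 8)
  s2 <- simulate_counts(p_ref, spec, seed = 8)
  expect_identical(s1$counts, s2$counts)
  c1 <- simulate_cohort(synthetic_spec(n_pairs = 2, seed = 5, truth_grid = 200))
  c2 <- simulate_cohort(synthetic_spec(n_pairs = 2, seed = 5, truth_grid = 200))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth, c2$truth)
})

test_that("noise is multiplicative lognormal with mean one", {
  # one condition replicated many times: the mean converges to the model value
  spec <- synthetic_spec(doses = c(0, 10), times = c(0, 48),
                         replicates = 10000, noise_cv = 0.05)
  sim <- withr::with_seed(17, {
    grid_val <- grivus:::model_counts(p_ref, 10, 48)
    counts <- grid_val * grivus:::noise_factor(10000, 0.05)
    list(mean = mean(counts), target = grid_val, sd = sd(counts / grid_val))
  })
  expect_equal(sim$mean, sim$target, tolerance = 0.005)
  expect_equal(sim$sd, 0.05, tolerance = 0.05)
})

test_that("outlier injection corrupts exactly the chosen rows", {
  sim <- sim_clean(p_ref)
  n <- nrow(sim$counts)  # 738 rows
  out0 <- inject_outliers(sim$counts, rate = 0, seed = 1)
  expect_equal(out0$count, sim$counts$count)
  expect_length(attr(out0, "outlier_rows"), 0)
  rate3 <- 3 / n
  out <- inject_outliers(sim$counts, rate = rate3, multiplier = 5, seed = 2)
  idx <- attr(out, "outlier_rows")
  expect_length(idx, 3)
  expect_equal(out$count[idx], 5 * sim$counts$count[idx])
  expect_identical(out$count[-idx], sim$counts$count[-idx])
  expect_error(inject_outliers(sim$counts, rate = 1), "rate")
})

test_that("GRIVUS resists strong outliers better than the endpoint dose-response AUC", {
  # 5% of wells at 5x emulates segmentation artefacts; the volume score
  # integrates over the whole time course while the endpoint AUC hangs on
  # the 18 wells of the final frame
  spec <- synthetic_spec(n_pairs = 10, noise_cv = 0.05, seed = 404,
                         truth_grid = 200)
  sim <- simulate_cohort(spec)
  endpoint_auc <- function(counts) {
    last <- counts[counts$time_h == max(counts$time_h) &
                     counts$concentration_uM > 0, ]
    curve <- dplyr::summarise(dplyr::group_by(last, .data$concentration_uM),
                              y = mean(.data$count), .groups = "drop")
    curve <- dplyr::arrange(curve, .data$concentration_uM)
    d <- log10(curve$concentration_uM)
    sum(diff(d) * (utils::head(curve$y, -1) + utils::tail(curve$y, -1)) / 2)
  }
  deltas <- purrr::imap_dfr(
    dplyr::group_split(dplyr::group_by(sim$counts, .data$drug)),
    function(g, i) {
      dirty <- inject_outliers(g, rate = 0.05, multiplier = 5, seed = 500 + i)
      g_clean <- grivus_scores(fit_dose_time(g), n_dose = 50, n_time = 50)$grivus_normalized
      g_dirty <- grivus_scores(fit_dose_time(dirty), n_dose = 50, n_time = 50)$grivus_normalized
      tibble::tibble(
        d_grivus = abs(g_dirty - g_clean) / g_clean,
        d_auc = abs(endpoint_auc(dirty) - endpoint_auc(g)) / endpoint_auc(g))
    })
  expect_lt(median(deltas$d_grivus), median(deltas$d_auc))
})
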