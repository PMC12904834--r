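#' Specification of a synthetic imaging plate
#'
#' Describes the layout and noise structure of simulated live-cell
#' imaging time courses: six concentration levels spanning 0-10 uM
#' (0 = vehicle control; non-zero doses a geometric ladder of ratio 5),
#' one image every 3 h over 120 h, three replicate wells per condition,
#' and multiplicative lognormal measurement noise with mean 1. Parameter
#' ranges default to realistic values for adherent tumour lines under an
#' inhibitor screen: untreated doubling times of 20-40 h
#' (`k_alpha` in `[0.025, 0.05]` per hour), growth plateaus of 5-20 fold,
#' treated growth between stasis and mild growth, and midpoint
#' concentrations inside the tested range.
#'
#' @param n_pairs Number of cell line-drug pairs in a cohort.
#' @param doses Tested concentrations in uM, including 0.
#' @param times Imaging times in hours, including 0.
#' @param replicates Wells per (dose, time) condition.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (mean 1); 0 disables noise.
#' @param outlier_rate Fraction of rows to corrupt in
#'   [inject_outliers()].
#' @param outlier_multiplier Fold change applied to corrupted rows.
#' @param ranges Named list of `c(lower, upper)` ranges for each of the
#'   six surface parameters, sampled uniformly by [sample_params()].
#' @param seed Integer seed used by [simulate_cohort()].
#' @param truth_grid Grid cells per axis for the fine-grid ground-truth
#'   GRIVUS recorded alongside each simulated pair.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pairs = 30,
                           doses = c(0, 0.016, 0.08, 0.4, 2, 10),
                           times = seq(0, 120, by = 3),
                           replicates = 3,
                           noise_cv = 0.05,
                           outlier_rate = 0,
                           outlier_multiplier = 5,
                           ranges = list(
                             k_alpha = c(0.025, 0.05),
                             a_alpha = c(5, 20),
                             k_delta = c(0, 0.03),
                             a_delta = c(1, 5),
                             k_beta = c(0.5, 2),
                             k_gamma = c(log10(0.016), 1)
                           ),
                           seed = 1L,
                           truth_grid = 1000) {
  if (!0 %in% doses) stop("doses must include the 0 uM vehicle control", call. = FALSE)
  if (!0 %in% times) stop("times must include t = 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("outlier_rate must be in [0, 1)", call. = FALSE)
  }
  miss <- setdiff(param_names(), names(ranges))
  if (length(miss)) stop("ranges missing: ", paste(miss, collapse = ", "), call. = FALSE)
  structure(
    list(n_pairs = as.integer(n_pairs), doses = sort(doses), times = sort(times),
         replicates = as.integer(replicates), noise_cv = noise_cv,
         outlier_rate = outlier_rate, outlier_multiplier = outlier_multiplier,
         ranges = ranges, seed = as.integer(seed),
         truth_grid = as.integer(truth_grid)),
    class = "synthetic_spec"
  )
}

#' Draw a random parameter set within the spec's ranges
#'
#' Uniform draws within each range, with rejection of combinations that
#' violate the surface's validity constraints (positive plateaus, pole
#' freedom, non-negative steepness factor); consumes the current RNG
#' stream, so results are deterministic given the RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @return A [dtr_params] object.
#' @export
sample_params <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in seq_len(1000L)) {
    draw <- lapply(spec$ranges[param_names()],
                   function(r) stats::runif(1, r[1], r[2]))
    p <- try(do.call(dtr_params, draw), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
  stop("could not draw valid parameters from the given ranges", call. = FALSE)
}

# lognormal with mean exactly 1 and the requested CV
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one cell line-drug time course from known parameters
#'
#' Counts are the surface values at each (dose, time) -- the control
#' wells follow `alpha(t)` -- multiplied by lognormal noise with mean 1
#' and CV `noise_cv`. Noise is applied at `t = 0` too (where the model
#' value is exactly 1), and the pair is then re-normalised with
#' [normalize_initial()], mirroring how a real plate is processed. The
#' returned ground truth records the generating parameters and their
#' fine-grid normalised GRIVUS over the tested dose range and full time
#' window.
#'
#' @param params Generating [dtr_params].
#' @param spec A [synthetic_spec()]; layout and noise are taken from it.
#' @param cell_line,drug Identifiers written into the table.
#' @param seed Optional integer seed; if `NULL` the current RNG stream
#'   is consumed (for cohort-level seeding).
#' @return List with `counts` (long-format tibble: `cell_line`, `drug`,
#'   `concentration_uM`, `time_h`, `replicate`, `count`) and `truth`
#'   (list: `params`, `grivus_normalized`, `model_counts`).
#' @export
simulate_counts <- function(params, spec, cell_line = "SIM", drug = "drug01",
                            seed = NULL) {
  params <- as_dtr_params(params)
  stopifnot(inherits(spec, "synthetic_spec"))
  run <- function() {
    grid <- tidyr::expand_grid(
      concentration_uM = spec$doses,
      time_h = spec$times,
      replicate = sprintf("r%d", seq_len(spec$replicates))
    )
    truth_counts <- model_counts(params, grid$concentration_uM, grid$time_h)
    counts <- truth_counts * noise_factor(nrow(grid), spec$noise_cv)
    out <- tibble::tibble(
      cell_line = cell_line, drug = drug,
      concentration_uM = grid$concentration_uM,
      time_h = grid$time_h,
      replicate = grid$replicate,
      count = counts
    )
    out <- normalize_initial(out)
    dd <- dose_domain(spec$doses)
    dom <- integration_domain(dd[1], dd[2], 0, max(spec$times),
                              spec$truth_grid, spec$truth_grid)
    list(counts = out,
         truth = list(params = params,
                      grivus_normalized = grivus(params, dom)$grivus_normalized,
                      model_counts = truth_counts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort of cell line-drug pairs
#'
#' Draws `n_pairs` parameter sets and simulates one plate per pair,
#' fully determined by `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (all pairs stacked) and `truth` (tibble:
#'   one row per pair with the generating parameters and the fine-grid
#'   normalised GRIVUS).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    sims <- purrr::map(seq_len(spec$n_pairs), function(i) {
      p <- sample_params(spec)
      sim <- simulate_counts(p, spec, cell_line = "SIM1",
                             drug = sprintf("drug%02d", i))
      list(counts = sim$counts,
           truth = tibble::tibble(
             cell_line = "SIM1", drug = sprintf("drug%02d", i),
             !!!as.list(unlist(sim$truth$params[param_names()])),
             grivus_true = sim$truth$grivus_normalized))
    })
    list(counts = dplyr::bind_rows(purrr::map(sims, "counts")),
         truth = dplyr::bind_rows(purrr::map(sims, "truth")))
  })
}

#' Corrupt a fraction of rows with multiplicative outliers
#'
#' Picks `round(rate * nrow)` rows without replacement and multiplies
#' their counts by `multiplier`, emulating segmentation artefacts such
#' as debris or focus loss; used to probe the robustness of volume-based
#' scores against endpoint AUC. The chosen row indices are attached as
#' attribute `"outlier_rows"`.
#'
#' @param data Count tibble.
#' @param rate Fraction of rows to corrupt, in `[0, 1)`.
#' @param multiplier Fold change applied to the chosen counts.
#' @param seed Optional seed for the row choice.
#' @return The corrupted tibble with attribute `outlier_rows` (sorted
#'   integer row indices; empty when `rate = 0`).
#' @export
inject_outliers <- function(data, rate = 0.05, multiplier = 5, seed = NULL) {
  check_count_columns(data)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  n_out <- round(rate * nrow(data))
  pick <- function() sort(sample.int(nrow(data), n_out))
  idx <- if (n_out == 0) integer(0)
         else if (is.null(seed)) pick()
         else withr::with_seed(seed, pick())
  data$count[idx] <- data$count[idx] * multiplier
  attr(data, "outlier_rows") <- idx
  data
}
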