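#' Restrict a count table to an initial time window
#'
#' Keeps exactly the rows with `time_h <= t_max`, preserving row order
#' and all dose levels; used to fit on a short incubation window before
#' extrapolating.
#'
#' @param data Count tibble (long format).
#' @param t_max End of the training window in hours (`> 0`).
#' @return The filtered tibble.
#' @export
truncate_counts <- function(data, t_max) {
  check_count_columns(data)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  out <- data[data$time_h <= t_max, , drop = FALSE]
  n_times <- if (all(c("cell_line", "drug") %in% names(out)) && nrow(out)) {
    min(dplyr::summarise(dplyr::group_by(out, .data$cell_line, .data$drug),
                         n = dplyr::n_distinct(.data$time_h))$n)
  } else {
    dplyr::n_distinct(out$time_h)
  }
  if (nrow(out) == 0 || n_times < 2) {
    stop("truncation at t_max = ", t_max,
         " leaves fewer than 2 distinct time points", call. = FALSE)
  }
  out
}

#' Extrapolated GRIVUS of a trained surface over a longer horizon
#'
#' Evaluates the GRIVUS of parameters fitted on a short window over a
#' (typically longer) horizon domain; a pure function of the parameters
#' and the domain.
#'
#' @param fit_train A `dtr_fit` from the truncated window.
#' @param dom_horizon An [integration_domain] whose `t_max` is the
#'   prediction horizon.
#' @return A `grivus_result`.
#' @export
predict_response <- function(fit_train, dom_horizon) {
  stopifnot(inherits(fit_train, "dtr_fit"))
  grivus(fit_train$params, dom_horizon)
}

predict_pair <- function(data, t_train, t_horizon, options, n_dose, n_time,
                         holdout_only = FALSE,
                         cell_line = NA_character_, drug = NA_character_) {
  train <- truncate_counts(data, t_train)
  fit_train <- fit_pair(train, options, cell_line = cell_line, drug = drug)
  fit_full <- fit_pair(data, options, cell_line = cell_line, drug = drug)

  dd <- dose_domain(data$concentration_uM)
  dom_train <- integration_domain(dd[1], dd[2], 0, t_train, n_dose, n_time)
  dom_horizon <- integration_domain(dd[1], dd[2], 0, t_horizon, n_dose, n_time)

  g_train <- grivus(fit_train$params, dom_train)
  g_pred <- grivus(fit_train$params, dom_horizon)
  g_meas <- grivus(fit_full$params, dom_horizon)

  eval_rows <- if (holdout_only) {
    data[data$time_h > t_train, , drop = FALSE]
  } else {
    data
  }
  mape_holdout <- mape(eval_rows$count,
                       model_counts(fit_train$params,
                                    eval_rows$concentration_uM,
                                    eval_rows$time_h))
  trend <- sign(g_pred$grivus_normalized - g_train$grivus_normalized) ==
    sign(g_meas$grivus_normalized - g_train$grivus_normalized)

  tibble::tibble(
    cell_line = cell_line, drug = drug,
    t_train = t_train, t_horizon = t_horizon,
    mape_train_percent = fit_train$mape_percent,
    mape_full_percent = fit_full$mape_percent,
    mape_holdout_percent = mape_holdout,
    grivus_at_train = g_train$grivus_normalized,
    grivus_predicted = g_pred$grivus_normalized,
    grivus_measured = g_meas$grivus_normalized,
    trend_agrees = trend,
    fit_train = list(fit_train),
    fit_full = list(fit_full)
  )
}

#' Fit on a short window and extrapolate GRIVUS to a later horizon
#'
#' Per cell line-drug pair: fits the surface to the data up to
#' `t_train`, extrapolates the trained parameters to `t_horizon`, and
#' compares against the "measured" GRIVUS -- the GRIVUS of a fresh fit
#' to the complete time course (not a direct data integral). The holdout
#' MAPE is the trained surface's MAPE against all measured counts over
#' the full window `[0, t_horizon]`, which makes it directly comparable
#' with the full-window fit MAPE; set `holdout_only = TRUE` to score
#' only the unseen rows with `time_h > t_train`.
#'
#' `trend_agrees` records whether the predicted change in GRIVUS between
#' the training window and the horizon has the same sign as the measured
#' change.
#'
#' @param data Count tibble covering times beyond `t_train` (normalised;
#'   optionally with `cell_line`/`drug` columns for multi-pair tables).
#' @param t_train Training window end in hours (default 72).
#' @param t_horizon Prediction horizon in hours (default 120).
#' @param options [fit_options()] used for both fits.
#' @param n_dose,n_time GRIVUS grid resolution (default 100 x 100).
#' @param holdout_only Score the holdout MAPE only on rows after
#'   `t_train` (default `FALSE`).
#' @return Tibble with one row per pair: training/full/holdout MAPEs,
#'   GRIVUS at the training window, predicted and measured GRIVUS at
#'   the horizon, the trend flag, and `fit_train`/`fit_full`
#'   list-columns.
#' @export
predict_grivus <- function(data, t_train = 72, t_horizon = 120,
                           options = fit_options(), n_dose = 100,
                           n_time = 100, holdout_only = FALSE) {
  stopifnot(is.data.frame(data))
  if (t_train >= t_horizon) stop("t_train must be < t_horizon", call. = FALSE)
  if (max(data$time_h) <= t_train) {
    stop("data must extend beyond t_train", call. = FALSE)
  }
  has_ids <- all(c("cell_line", "drug") %in% names(data))
  groups <- if (has_ids) {
    dplyr::group_split(dplyr::group_by(data, .data$cell_line, .data$drug))
  } else {
    list(data)
  }
  dplyr::bind_rows(purrr::map(groups, function(g) {
    predict_pair(g, t_train, t_horizon, options, n_dose, n_time,
                 holdout_only = holdout_only,
                 cell_line = if (has_ids) g$cell_line[1] else NA_character_,
                 drug = if (has_ids) g$drug[1] else NA_character_)
  }))
}
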