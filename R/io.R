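#' Read a long-format plate-count table
#'
#' Expects a UTF-8 CSV with header columns `cell_line`, `drug`,
#' `concentration_uM`, `time_h`, `replicate`, `count` (extra columns are
#' ignored; `col_map` renames non-standard headers). Malformed numeric
#' fields and negative concentrations, times or counts are reported with
#' their file line numbers.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping standard names
#'   to the file's headers, e.g.
#'   `c(concentration_uM = "conc", time_h = "elapsed")`.
#' @return Tibble sorted by (`cell_line`, `drug`, `concentration_uM`,
#'   `time_h`, `replicate`).
#' @export
read_counts <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        stop("col_map: column '", col_map[[std]], "' not found in ", path,
             call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  need <- c("cell_line", "drug", "concentration_uM", "time_h", "replicate", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- raw[need]
  # file line = data row + 1 (header)
  for (col in c("concentration_uM", "time_h", "count")) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(num) & !is.na(out[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " on line ",
           paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop("negative ", col, " on line ",
           paste(utils::head(neg + 1L, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    }
    out[[col]] <- num
  }
  dplyr::arrange(out, .data$cell_line, .data$drug, .data$concentration_uM,
                 .data$time_h, .data$replicate)
}

#' Normalise counts to an initial value of 1 per pair
#'
#' Divides every count of a cell line-drug pair by the mean count over
#' all of that pair's wells at its earliest time point, so each pair's
#' trajectory starts (on average) at exactly 1. Idempotent on
#' already-normalised data.
#'
#' @param data Count tibble (with or without `cell_line`/`drug`
#'   columns; without them the whole table is one pair).
#' @return The normalised tibble.
#' @export
normalize_initial <- function(data) {
  check_count_columns(data)
  norm_one <- function(g) {
    t0 <- min(g$time_h)
    ref <- mean(g$count[g$time_h == t0])
    if (!is.finite(ref) || ref <= 0) {
      stop("cannot normalise: non-positive mean count at earliest time t = ", t0,
           call. = FALSE)
    }
    g$count <- g$count / ref
    g
  }
  if (all(c("cell_line", "drug") %in% names(data))) {
    dplyr::bind_rows(purrr::map(
      dplyr::group_split(dplyr::group_by(data, .data$cell_line, .data$drug)),
      norm_one))
  } else {
    norm_one(data)
  }
}

#' Flag wells deviating from their pair at an early QC time point
#'
#' Compares each well's count at the time point nearest `t_check`
#' against the median over the pair's wells at that time; wells whose
#' relative deviation from the median exceeds `threshold` are flagged.
#' Flagging only -- exclusion is left to the caller.
#'
#' @param data Count tibble.
#' @param t_check QC time in hours (default 3; the nearest measured time
#'   is used).
#' @param threshold Relative deviation above which a well is flagged
#'   (default 0.30).
#' @return Tibble of flagged wells: `cell_line`, `drug`,
#'   `concentration_uM`, `replicate`, `count`, `pair_median`,
#'   `deviation`. Empty (with a warning) if no measurements exist.
#' @export
qc_flag_wells <- function(data, t_check = 3, threshold = 0.30) {
  check_count_columns(data)
  if (!"replicate" %in% names(data)) data$replicate <- "r1"
  if (!"cell_line" %in% names(data)) data$cell_line <- "all"
  if (!"drug" %in% names(data)) data$drug <- "all"
  if (nrow(data) == 0) {
    warning("no measurements to QC")
    return(tibble::tibble(cell_line = character(), drug = character(),
                          concentration_uM = numeric(), replicate = character(),
                          count = numeric(), pair_median = numeric(),
                          deviation = numeric()))
  }
  flags <- purrr::map(
    dplyr::group_split(dplyr::group_by(data, .data$cell_line, .data$drug)),
    function(g) {
      tt <- unique(g$time_h)
      t_near <- tt[which.min(abs(tt - t_check))]
      at_t <- g[g$time_h == t_near, , drop = FALSE]
      med <- stats::median(at_t$count)
      at_t$pair_median <- med
      at_t$deviation <- abs(at_t$count - med) / med
      at_t[at_t$deviation > threshold,
           c("cell_line", "drug", "concentration_uM", "replicate",
             "count", "pair_median", "deviation")]
    })
  dplyr::bind_rows(flags)
}

#' Write / read fitted parameter tables
#'
#' `write_params()` saves the per-pair parameter columns of a
#' [fit_dose_time()] result as CSV; `read_params()` loads such a table
#' back. A written-then-read table reproduces the fitted surfaces
#' exactly (full double precision is retained).
#'
#' @param fits Tibble from [fit_dose_time()] (or any tibble with the six
#'   parameter columns and `cell_line`/`drug`).
#' @param path CSV path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a tibble with one [dtr_params] per row in a `params`
#'   list-column.
#' @export
write_params <- function(fits, path) {
  cols <- c("cell_line", "drug", param_names(),
             intersect(c("mape_percent", "n_points", "converged"), names(fits)))
  readr::write_csv(fits[intersect(cols, names(fits))], path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  miss <- setdiff(param_names(), names(tab))
  if (length(miss)) {
    stop("parameter table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$params <- purrr::pmap(tab[param_names()], dtr_params)
  tab
}

#' Configuration for an end-to-end pipeline run
#'
#' @param input Path to the input count CSV (schema of [read_counts()]).
#' @param output_dir Directory for report files (created if absent).
#' @param t_train,t_horizon Training window and prediction horizon in
#'   hours.
#' @param n_dose,n_time GRIVUS grid (default 100 x 100 = 10 000 cuboids).
#' @param seed Seed for the bootstrap CI.
#' @param n_boot Bootstrap repetitions for the cohort CCC.
#' @param loss Fitting loss (see [fit_options()]).
#' @param qc_threshold Relative deviation for [qc_flag_wells()].
#' @param interval Optional imaging cadence in hours; if given, the data
#'   are subsampled to times that are multiples of `interval` before
#'   analysis (e.g. 24 to emulate daily imaging).
#' @param col_map Passed to [read_counts()].
#' @return A `run_config` list.
#' @export
run_config <- function(input, output_dir, t_train = 72, t_horizon = 120,
                       n_dose = 100, n_time = 100, seed = 1L, n_boot = 100,
                       loss = "squared_relative", qc_threshold = 0.30,
                       interval = NULL, col_map = NULL) {
  if (t_train >= t_horizon) stop("t_train must be < t_horizon", call. = FALSE)
  structure(
    list(input = input, output_dir = output_dir, t_train = t_train,
         t_horizon = t_horizon, n_dose = n_dose, n_time = n_time,
         seed = as.integer(seed), n_boot = as.integer(n_boot), loss = loss,
         qc_threshold = qc_threshold, interval = interval, col_map = col_map),
    class = "run_config"
  )
}

#' Subsample a count table to a coarser imaging cadence
#'
#' Keeps rows whose time is a whole multiple of `interval` hours.
#'
#' @param data Count tibble.
#' @param interval Cadence in hours.
#' @return The filtered tibble.
#' @export
subsample_interval <- function(data, interval) {
  check_count_columns(data)
  data[data$time_h %% interval == 0, , drop = FALSE]
}

#' Run the full screen analysis and write report files
#'
#' Reads and normalises the input table, flags QC outlier wells (flag
#' only), fits every cell line-drug pair on the training window and the
#' full window, computes GRIVUS at the training window plus predicted
#' and measured GRIVUS at the horizon, and writes: `params.csv` (full-
#' window fits), `predictions.csv` (per-pair report), `qc_flags.csv`,
#' `concordance.csv` (cohort CCC with bootstrap CI between predicted and
#' measured GRIVUS), and `run_metadata.yml`. Per-pair failures are
#' caught, logged to standard error and recorded in `failures.csv`
#' without aborting the cohort. Deterministic given the config:
#' repeated runs produce byte-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-pair report tibble and the
#'   cohort concordance.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_counts(config$input, col_map = config$col_map)
  if (!is.null(config$interval)) {
    counts <- subsample_interval(counts, config$interval)
  }
  counts <- normalize_initial(counts)
  flags <- qc_flag_wells(counts, threshold = config$qc_threshold)
  readr::write_csv(flags, file.path(config$output_dir, "qc_flags.csv"))

  opts <- fit_options(loss = config$loss)
  groups <- dplyr::group_split(dplyr::group_by(counts, .data$cell_line, .data$drug))
  reports <- list()
  failures <- list()
  for (g in groups) {
    id <- paste(g$cell_line[1], g$drug[1], sep = " / ")
    message("fitting ", id)
    res <- tryCatch(
      predict_grivus(g, t_train = config$t_train, t_horizon = config$t_horizon,
                     options = opts, n_dose = config$n_dose,
                     n_time = config$n_time),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      message("  failed: ", conditionMessage(res))
      failures[[length(failures) + 1L]] <- tibble::tibble(
        cell_line = g$cell_line[1], drug = g$drug[1],
        error = conditionMessage(res))
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  report <- dplyr::bind_rows(reports)
  readr::write_csv(
    dplyr::bind_rows(failures,
                     tibble::tibble(cell_line = character(), drug = character(),
                                    error = character())),
    file.path(config$output_dir, "failures.csv"))

  if (nrow(report)) {
    full_fits <- dplyr::bind_rows(purrr::map(report$fit_full, function(f) {
      tibble::tibble(cell_line = f$data$cell_line, drug = f$data$drug,
                     !!!as.list(unlist(f$params[param_names()])),
                     mape_percent = f$mape_percent, n_points = f$n_points,
                     converged = f$converged)
    }))
    write_params(full_fits, file.path(config$output_dir, "params.csv"))
    readr::write_csv(dplyr::select(report, -"fit_train", -"fit_full"),
                     file.path(config$output_dir, "predictions.csv"))
  }

  conc <- NULL
  if (nrow(report) >= 2) {
    conc <- concordance(report$grivus_measured, report$grivus_predicted,
                        n_boot = config$n_boot, seed = config$seed)
    readr::write_csv(
      tibble::tibble(comparison = "grivus_measured_vs_predicted",
                     ccc = conc$ccc, pcc = conc$pcc, ci_low = conc$ci_low,
                     ci_high = conc$ci_high, n = conc$n, n_boot = conc$n_boot,
                     level = conc$level),
      file.path(config$output_dir, "concordance.csv"))
  }

  meta <- config[c("input", "t_train", "t_horizon", "n_dose", "n_time",
                   "seed", "n_boot", "loss", "qc_threshold")]
  meta$interval <- config$interval %||% "native"
  meta$package_version <- as.character(utils::packageVersion("grivus"))
  meta$n_pairs <- length(groups)
  meta$n_failed <- length(failures)
  yaml::write_yaml(meta, file.path(config$output_dir, "run_metadata.yml"))

  invisible(list(report = report, concordance = conc, qc_flags = flags))
}
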