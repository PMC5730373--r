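trace_table_cols <- c("cell_id", "time_min", "reporter", "value",
                      "condition", "replicate", "treatment_time_min")

validate_trace_table <- function(df) {
  missing_cols <- setdiff(trace_table_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("trace table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- df %>%
    dplyr::count(.data$cell_id, .data$time_min, .data$reporter) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (cell_id, time_min, reporter) rows, e.g. ",
                 dup$cell_id[1], " @ ", dup$time_min[1]))
  }
  bad <- df %>%
    group_by(.data$cell_id, .data$reporter) %>%
    summarise(irregular = {
      t <- sort(unique(.data$time_min))
      length(t) > 2 && diff(range(diff(t))) > 1e-9
    }, .groups = "drop") %>%
    filter(.data$irregular)
  if (nrow(bad) > 0) {
    abort(paste0("non-uniform time grid for cell(s): ",
                 paste(unique(bad$cell_id), collapse = ", ")))
  }
  invisible(df)
}

#' Read / write the long-format trace table
#'
#' The interchange format for single-cell trace populations: one row per
#' cell, time point and reporter, with columns `cell_id`, `time_min`,
#' `reporter`, `value` (empty = missing), `condition`, `replicate`,
#' `treatment_time_min`. Reading validates uniqueness of
#' (cell_id, time_min, reporter) and per-cell grid uniformity; the
#' write/read round trip is lossless.
#'
#' @param path CSV file path.
#' @return `read_trace_table` returns a `trace_tbl`.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          reporter = readr::col_character(),
                          condition = readr::col_character(),
                          replicate = readr::col_character(),
                          .default = readr::col_double()))
  validate_trace_table(df)
  new_trace_tbl(df)
}

#' @rdname read_trace_table
#' @param traces a `trace_tbl` (or plain data frame with the same columns).
#' @export
write_trace_table <- function(traces, path) {
  df <- as_tibble(traces)[, trace_table_cols]
  validate_trace_table(df)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

default_config <- function() {
  list(
    window_min = 40,          # pulse-detection sliding window (min)
    smooth = 3,               # smoothing span (samples)
    f_hi = 0.7,               # upper cutoff fraction of local range
    f_lo = 0.3,               # lower cutoff fraction of local range
    min_amp = NA,             # amplitude floor; NA = 4 x noise scale
    max_spacing_min = 60,     # run spacing bound for oscillation calls
    min_pulses = 5,           # pulses needed for a defined period
    adapt_within_min = 120,   # adaptation window after treatment
    pre_window_min = 60,      # pre-treatment baseline window
    return_frac = 0.25,       # return-to-baseline threshold fraction
    detrend_window_min = 120, # detrending window for correlations
    lock_tol_frac = 0.5,      # phase-lock nearest-peak proximity
    lock_count_tol = 0.1,     # phase-lock count agreement
    lock_lag_sd_frac = 0.15,  # phase-lock lag dispersion bound
    seed = 1,
    log_level = "info"
  )
}

#' Read an analysis configuration file
#'
#' Plain-text YAML key-value configuration. Absent keys take the documented
#' defaults; unknown keys are rejected with a suggestion for the nearest
#' valid key; values must match the type of the default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of effective settings (class `run_config`).
#' @examples
#' cfg <- read_config(NULL)
#' cfg$window_min
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste("config file not found:", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (key in names(user)) {
      if (!key %in% names(cfg)) {
        sugg <- agrep(key, names(cfg), max.distance = 0.3, value = TRUE)
        hint <- if (length(sugg) > 0) {
          paste0("; did you mean '", sugg[1], "'?")
        } else ""
        abort(paste0("unknown config key '", key, "'", hint))
      }
      val <- user[[key]]
      if (is.character(cfg[[key]]) && !is.character(val)) {
        abort(paste0("config key '", key, "' must be a string"))
      }
      if (is.numeric(cfg[[key]]) && !is.numeric(val) &&
          !(is.logical(val) && is.na(val))) {
        abort(paste0("config key '", key, "' must be numeric"))
      }
      cfg[[key]] <- val
    }
  }
  structure(cfg, class = "run_config")
}

#' Write the effective configuration next to run outputs
#' @param cfg a `run_config`.
#' @param dir output directory.
#' @return invisibly, the written path.
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "effective_config.yaml")
  yaml::write_yaml(unclass(cfg), p)
  invisible(p)
}
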