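#' Moving-average smoothing of a trace
#'
#' Centered moving average of width `span` samples. An even `span` is reduced
#' to the next odd width (the usual moving-average convention), and the window
#' shrinks symmetrically at the trace ends so no samples are lost. `span = 1`
#' is the identity.
#'
#' @param x numeric vector of index values.
#' @param span window width in samples (integer, >= 1).
#' @return smoothed numeric vector, same length as `x`.
#' @export
smooth_trace <- function(x, span = 3) {
  if (!is.numeric(span) || length(span) != 1L || span < 1 ||
      span != round(span)) {
    abort("span must be a positive integer")
  }
  n <- length(x)
  h <- floor((span - 1) / 2)
  if (h == 0L || n == 0L) return(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

#' Robust noise-scale estimate for a trace
#'
#' Estimates the standard deviation of the high-frequency measurement noise
#' from first differences, blockwise: within each block of `block` successive
#' differences the scale is `1.4826 * median(|diff|) / sqrt(2)` (the Gaussian
#' MAD calibration for a differenced series), and the reported scale is the
#' minimum over blocks. Taking the quietest block keeps the estimate anchored
#' to measurement noise even when most of the trace is covered by genuine
#' pulses, whose sample-to-sample changes would otherwise inflate a global
#' difference-based estimate; a trace that oscillates everywhere still needs
#' only one quiet stretch (e.g. the pre-treatment baseline) for an honest
#' estimate.
#'
#' @param x numeric vector (raw, unsmoothed trace).
#' @param block number of differences per block (default 40, i.e. 2 hr at
#'   3-min sampling).
#' @return scalar noise standard-deviation estimate.
#' @export
noise_scale <- function(x, block = 40) {
  x <- x[!is.na(x)]
  d <- abs(diff(x))
  if (length(d) == 0L) return(0)
  if (length(d) < 2 * block) {
    return(1.4826 * median(d) / sqrt(2))
  }
  nb <- floor(length(d) / block)
  idx <- rep(seq_len(nb), each = block)
  s <- vapply(split(d[seq_len(nb * block)], idx),
              function(b) 1.4826 * median(b) / sqrt(2), numeric(1))
  min(s)
}

rolling_range <- function(x, hw) {
  n <- length(x)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - hw):min(n, i + hw)]
    lo[i] <- min(w)
    hi[i] <- max(w)
  }
  list(min = lo, max = hi)
}

#' Detect pulses in a single smoothed trace
#'
#' Sliding-window two-cutoff peak detector. At every sample the local minimum
#' `m` and maximum `M` over a centered window define a lower cutoff
#' `m + f_lo * (M - m)` and an upper cutoff `m + f_hi * (M - m)` (truncated
#' windows at the trace ends). A pulse is emitted for every excursion that
#' rises from below the lower cutoff to above the upper cutoff and falls back
#' below the lower cutoff. The peak is the excursion maximum (earliest sample
#' on a plateau); the pulse baseline is the trace minimum between the end of
#' the previous pulse (or the trace start) and the peak; the amplitude is
#' peak minus baseline. Pulses with amplitude below `min_amp` are suppressed.
#'
#' @param time numeric vector of times (minutes, uniform grid).
#' @param value numeric trace (smooth first with [smooth_trace()]).
#' @param window sliding-window width in minutes (default 40).
#' @param f_hi,f_lo upper/lower cutoff fractions of the local range.
#' @param min_amp minimum pulse amplitude in index units; `NULL` (default)
#'   uses `4 * noise_scale(value)`.
#' @return tibble with one row per pulse: `peak_time`, `peak_value`,
#'   `baseline_value`, `amplitude`, `start_time`, `end_time`, `duration`.
#' @export
detect_pulses <- function(time, value, window = 40, f_hi = 0.7, f_lo = 0.3,
                          min_amp = NULL) {
  stopifnot(length(time) == length(value))
  keep <- !is.na(value)
  time <- time[keep]
  value <- value[keep]
  n <- length(value)
  empty <- tibble(peak_time = numeric(), peak_value = numeric(),
                  baseline_value = numeric(), amplitude = numeric(),
                  start_time = numeric(), end_time = numeric(),
                  duration = numeric())
  if (n < 3L) return(empty)
  dt <- median(diff(time))
  if (window < 2 * dt) abort("window must be at least 2 * dt")
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= 1)) {
    abort("cutoff fractions must satisfy 0 <= f_lo < f_hi <= 1")
  }
  if (n * dt < window) {
    warn("trace shorter than the detection window; no pulses detected")
    return(empty)
  }
  if (is.null(min_amp)) min_amp <- 4 * noise_scale(value)

  hw <- max(1L, round(window / (2 * dt)))
  rr <- rolling_range(value, hw)
  lo <- rr$min + f_lo * (rr$max - rr$min)
  hi <- rr$min + f_hi * (rr$max - rr$min)

  state <- 0L    # 0 waiting to arm, 1 armed, 2 inside pulse
  arm_idx <- NA_integer_
  prev_end <- 1L
  rows <- list()
  for (i in seq_len(n)) {
    if (state == 0L) {
      if (value[i] < lo[i]) { state <- 1L; arm_idx <- i }
    } else if (state == 1L) {
      if (value[i] < lo[i]) arm_idx <- i
      if (value[i] > hi[i]) { state <- 2L; start_idx <- arm_idx }
    } else {
      if (value[i] < lo[i]) {
        seg <- start_idx:i
        peak_idx <- seg[which.max(value[seg])]
        base_seg <- prev_end:peak_idx
        baseline <- min(value[base_seg])
        rows[[length(rows) + 1L]] <- c(
          peak_idx = peak_idx, start_idx = start_idx, end_idx = i,
          baseline = baseline)
        prev_end <- i
        state <- 1L
        arm_idx <- i
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  out <- tibble(
    peak_time = time[m[, "peak_idx"]],
    peak_value = value[m[, "peak_idx"]],
    baseline_value = m[, "baseline"],
    amplitude = value[m[, "peak_idx"]] - m[, "baseline"],
    start_time = time[m[, "start_idx"]],
    end_time = time[m[, "end_idx"]],
    duration = time[m[, "end_idx"]] - time[m[, "start_idx"]]
  )
  out[out$amplitude >= min_amp, ]
}

#' Pulse score: cumulative pulse intensity per hour
#'
#' Sum of detected pulse amplitudes normalized by the recording length, in
#' index units per hour. Grows with both the frequency and the amplitude of
#' pulses; a flat trace scores 0.
#'
#' @param pulses pulse tibble from [detect_pulses()].
#' @param recorded_duration length of the recording in minutes.
#' @return scalar score (index units / hr).
#' @export
pulse_score <- function(pulses, recorded_duration) {
  if (!is.numeric(recorded_duration) || recorded_duration <= 0) {
    abort("recorded_duration must be positive (minutes)")
  }
  if (is.null(pulses) || nrow(pulses) == 0L) return(0)
  sum(pulses$amplitude) / (recorded_duration / 60)
}

#' Mean oscillation period from peak-to-peak spacing
#'
#' Average spacing between successive pulse peaks, defined only for cells
#' with at least `min_pulses` pulses.
#'
#' @param pulses pulse tibble (time-ordered).
#' @param min_pulses minimum number of pulses required (default 5).
#' @return period in minutes, or `NA` if fewer than `min_pulses` pulses.
#' @export
mean_period <- function(pulses, min_pulses = 5) {
  if (is.null(pulses) || nrow(pulses) < min_pulses) return(NA_real_)
  mean(diff(pulses$peak_time))
}

#' Longest run of pulses with bounded spacing
#'
#' Length of the longest consecutive series of pulses whose successive
#' peak-to-peak spacings are all at most `max_spacing` minutes.
#'
#' @param pulses pulse tibble (time-ordered).
#' @param max_spacing maximum allowed spacing in minutes (default 60).
#' @return integer count (0 for no pulses, 1 for a single pulse).
#' @export
longest_pulse_run <- function(pulses, max_spacing = 60) {
  np <- if (is.null(pulses)) 0L else nrow(pulses)
  if (np == 0L) return(0L)
  if (np == 1L) return(1L)
  ok <- diff(pulses$peak_time) <= max_spacing
  r <- rle(ok)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) return(1L)
  as.integer(max(runs) + 1L)
}

#' Classify a cell as oscillatory
#'
#' A cell is oscillatory when it shows five or more successive pulses spaced
#' one hour or less apart.
#'
#' @inheritParams longest_pulse_run
#' @param min_run minimum run length (default 5).
#' @return logical flag.
#' @export
classify_oscillatory <- function(pulses, max_spacing = 60, min_run = 5) {
  longest_pulse_run(pulses, max_spacing) >= min_run
}

#' Time for a trace to return to its pre-treatment baseline
#'
#' The baseline is the mean of the smoothed trace over the `pre_window`
#' minutes before treatment. The initial response amplitude `A` is the
#' post-treatment maximum (within `response_window` minutes of treatment)
#' minus the baseline. The function returns the first time after that maximum
#' at which the smoothed trace drops to `baseline + return_frac * A`,
#' expressed as minutes since treatment, or `NA` if the trace never returns
#' (e.g. a sustained plateau).
#'
#' @param time,value trace vectors (minutes / index units).
#' @param treatment_time treatment time in minutes (must allow a full
#'   `pre_window` of pre-treatment samples).
#' @param pre_window pre-treatment baseline window, minutes.
#' @param return_frac fraction of the response amplitude defining return.
#' @param response_window window after treatment searched for the initial
#'   response maximum, minutes.
#' @param smooth_span smoothing span (samples) applied before measuring.
#' @return minutes since treatment, or `NA` if the trace never returns.
#' @export
time_to_baseline <- function(time, value, treatment_time, pre_window = 60,
                             return_frac = 0.25, response_window = 120,
                             smooth_span = 3) {
  keep <- !is.na(value)
  time <- time[keep]
  value <- value[keep]
  if (treatment_time - pre_window < min(time)) {
    abort("treatment_time must leave a full pre_window of samples")
  }
  x <- smooth_trace(value, smooth_span)
  pre <- time >= treatment_time - pre_window & time < treatment_time
  post <- time > treatment_time & time <= treatment_time + response_window
  if (!any(post)) abort("no post-treatment samples")
  baseline <- mean(x[pre])
  post_idx <- which(post)
  peak_idx <- post_idx[which.max(x[post_idx])]
  amp <- x[peak_idx] - baseline
  thresh <- baseline + return_frac * amp
  after <- which(seq_along(x) >= peak_idx & x <= thresh)
  if (length(after) == 0L) return(NA_real_)
  time[after[1]] - treatment_time
}

#' Fraction of cells adapting within a time window
#'
#' Fraction of cells whose index returns to baseline ([time_to_baseline()])
#' within `within` minutes of treatment, computed over cells that remain
#' alive (non-missing values) through the window.
#'
#' @param traces a `trace_tbl` (one reporter, shared treatment time).
#' @param within adaptation window in minutes (default 120).
#' @param reporter reporter channel to use (default `"AMPK"`).
#' @param ... passed to [time_to_baseline()].
#' @return scalar fraction in `[0, 1]`.
#' @export
adaptation_fraction <- function(traces, within = 120, reporter = "AMPK", ...) {
  df <- dplyr::filter(traces, .data$reporter == !!reporter)
  if (nrow(df) == 0L) abort("no traces for the requested reporter")
  tt <- unique(df$treatment_time_min)
  if (length(tt) != 1L) abort("all traces must share one treatment time")
  per_cell <- df %>%
    group_by(.data$cell_id) %>%
    group_split()
  returned <- alive <- logical(length(per_cell))
  for (i in seq_along(per_cell)) {
    d <- per_cell[[i]]
    ok <- !is.na(d$value)
    alive[i] <- any(ok) && max(d$time_min[ok]) >= tt + within
    if (alive[i]) {
      ttb <- time_to_baseline(d$time_min, d$value, tt, ...)
      returned[i] <- !is.na(ttb) && ttb <= within
    }
  }
  if (!any(alive)) abort("no cells alive through the adaptation window")
  mean(returned[alive])
}

#' Per-cell pulse summary for a trace population
#'
#' Smooths each trace, detects pulses and reduces them to the per-cell
#' summary used throughout the downstream analyses: pulse count, pulse score,
#' mean period, longest pulse run, oscillatory classification and (when a
#' treatment time is set) time to return to baseline.
#'
#' @param traces a `trace_tbl` (long format).
#' @param smooth_span smoothing span in samples (default 3).
#' @param window detection window in minutes (default 40).
#' @param f_hi,f_lo detection cutoff fractions.
#' @param min_amp minimum amplitude; `NULL` = noise-scaled default.
#' @param max_spacing run spacing bound in minutes (default 60).
#' @param min_pulses minimum pulses for a defined period (default 5).
#' @param after only count pulses with `peak_time > after` minutes; `NULL`
#'   (default) keeps all pulses.
#' @return tibble with one row per cell and reporter: `cell_id`, `reporter`,
#'   `condition`, `n_pulses`, `pulse_score`, `mean_period_min`,
#'   `longest_run`, `oscillatory`, `time_to_baseline_min`,
#'   `recorded_min`.
#' @examples
#' tr <- simulate_traces("ia_high", n_cells = 3, seed = 1)
#' summarize_pulses(tr)
#' @export
summarize_pulses <- function(traces, smooth_span = 3, window = 40,
                             f_hi = 0.7, f_lo = 0.3, min_amp = NULL,
                             max_spacing = 60, min_pulses = 5, after = NULL) {
  groups <- traces %>%
    as_tibble() %>%
    group_by(.data$cell_id, .data$reporter) %>%
    group_split()
  rows <- lapply(groups, function(d) {
    ok <- !is.na(d$value)
    t <- d$time_min[ok]
    v <- d$value[ok]
    cond <- d$condition[1]
    tt <- d$treatment_time_min[1]
    rec <- if (length(t) > 1) diff(range(t)) else 0
    if (length(t) < 3L) {
      return(tibble(cell_id = d$cell_id[1], reporter = d$reporter[1],
                    condition = cond, n_pulses = 0L, pulse_score = 0,
                    mean_period_min = NA_real_, longest_run = 0L,
                    oscillatory = FALSE, time_to_baseline_min = NA_real_,
                    recorded_min = rec))
    }
    # amplitude floor from the raw (unsmoothed) trace
    ma <- if (is.null(min_amp)) 4 * noise_scale(v) else min_amp
    p <- detect_pulses(t, smooth_trace(v, smooth_span), window = window,
                       f_hi = f_hi, f_lo = f_lo, min_amp = ma)
    if (!is.null(after)) p <- p[p$peak_time > after, ]
    ttb <- NA_real_
    if (!is.na(tt) && tt > 0 && tt - 60 >= min(t) && max(t) > tt) {
      ttb <- tryCatch(
        time_to_baseline(t, v, tt, smooth_span = smooth_span),
        error = function(e) NA_real_)
    }
    tibble(cell_id = d$cell_id[1], reporter = d$reporter[1],
           condition = cond, n_pulses = nrow(p),
           pulse_score = pulse_score(p, max(rec, 1e-9)),
           mean_period_min = mean_period(p, min_pulses),
           longest_run = longest_pulse_run(p, max_spacing),
           oscillatory = classify_oscillatory(p, max_spacing),
           time_to_baseline_min = ttb,
           recorded_min = rec)
  })
  bind_rows(rows)
}

#' Per-cell latency of the first post-treatment pulse
#'
#' Time from treatment to the first detected pulse peak, per cell.
#'
#' @inheritParams summarize_pulses
#' @return tibble with `cell_id`, `reporter`, `first_pulse_min` (NA when no
#'   pulse follows treatment).
#' @export
first_pulse_time <- function(traces, smooth_span = 3, window = 40,
                             f_hi = 0.7, f_lo = 0.3, min_amp = NULL) {
  groups <- traces %>%
    as_tibble() %>%
    group_by(.data$cell_id, .data$reporter) %>%
    group_split()
  rows <- lapply(groups, function(d) {
    ok <- !is.na(d$value)
    t <- d$time_min[ok]
    v <- d$value[ok]
    tt <- d$treatment_time_min[1]
    ma <- if (is.null(min_amp)) 4 * noise_scale(v) else min_amp
    p <- detect_pulses(t, smooth_trace(v, smooth_span), window = window,
                       f_hi = f_hi, f_lo = f_lo, min_amp = ma)
    p <- p[p$peak_time > tt, ]
    tibble(cell_id = d$cell_id[1], reporter = d$reporter[1],
           first_pulse_min = if (nrow(p) == 0) NA_real_ else
             p$peak_time[1] - tt)
  })
  bind_rows(rows)
}
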