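#' Moving-average detrending
#'
#' Subtracts a centered moving average of width `window` minutes, leaving a
#' near-zero-mean residual that preserves oscillations much faster than the
#' window while removing slow drift.
#'
#' @param value numeric trace.
#' @param dt sampling interval in minutes.
#' @param window detrending window in minutes (default 120; must be at least
#'   `2 * dt`).
#' @return detrended numeric vector.
#' @export
detrend_trace <- function(value, dt, window = 120) {
  if (window < 2 * dt) abort("detrend window must be at least 2 * dt")
  span <- 2L * floor(window / (2 * dt)) + 1L
  value - smooth_trace(value, span)
}

#' Per-cell correlation between two detrended channels
#'
#' Pearson correlation coefficient between two detrended series from the same
#' cell; the single-number-per-cell summary used to ask whether two reporters
#' co-fluctuate.
#'
#' @param a,b numeric vectors on the same time grid (detrended).
#' @param min_overlap minimum number of overlapping non-missing samples.
#' @return correlation in `[-1, 1]`, or `NA` if either channel has zero
#'   variance or the overlap is too short.
#' @export
cell_correlation <- function(a, b, min_overlap = 20) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) return(NA_real_)
  a <- a[ok]
  b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

split_pair <- function(traces, reporter_a, reporter_b) {
  df <- as_tibble(traces)
  have <- df %>%
    filter(.data$reporter %in% c(reporter_a, reporter_b)) %>%
    distinct(.data$cell_id, .data$reporter) %>%
    dplyr::count(.data$cell_id) %>%
    filter(.data$n == 2L)
  df %>% filter(.data$cell_id %in% have$cell_id)
}

pair_matrix <- function(df, cell, reporter_a, reporter_b) {
  d <- df[df$cell_id == cell, ]
  wide <- tidyr::pivot_wider(d[, c("time_min", "reporter", "value")],
                             names_from = "reporter", values_from = "value")
  wide <- arrange(wide, .data$time_min)
  list(time = wide$time_min, a = wide[[reporter_a]], b = wide[[reporter_b]])
}

#' Per-cell correlations between two reporters
#'
#' Detrends both channels of every cell carrying the two reporters and
#' computes the per-cell Pearson correlation ([cell_correlation()]).
#'
#' @param traces a `trace_tbl`.
#' @param reporter_a,reporter_b reporter channel names.
#' @param detrend_window detrending window in minutes.
#' @return tibble with `cell_id` and `r`.
#' @export
correlation_by_cell <- function(traces, reporter_a = "AMPK",
                                reporter_b = "Akt", detrend_window = 120) {
  df <- split_pair(traces, reporter_a, reporter_b)
  cells <- unique(df$cell_id)
  r <- vapply(cells, function(cl) {
    p <- pair_matrix(df, cl, reporter_a, reporter_b)
    ok <- !is.na(p$a) & !is.na(p$b)
    if (sum(ok) < 20) return(NA_real_)
    dt <- median(diff(p$time[ok]))
    cell_correlation(detrend_trace(p$a[ok], dt, detrend_window),
                     detrend_trace(p$b[ok], dt, detrend_window))
  }, numeric(1))
  tibble(cell_id = cells, r = unname(r))
}

#' Random-pairing null distribution of cross-reporter correlations
#'
#' Draws mismatched cell pairs (channel A from one cell, channel B from a
#' different cell) and computes the same detrended Pearson correlation as
#' [correlation_by_cell()], giving the negative-control distribution expected
#' when the two reporters carry no shared cell-intrinsic signal.
#'
#' @inheritParams correlation_by_cell
#' @param n_draws number of mismatched pairs to draw.
#' @param seed integer seed for the pairing draw.
#' @return tibble with `draw`, `cell_a`, `cell_b`, `r`.
#' @export
random_pairing_null <- function(traces, reporter_a = "AMPK",
                                reporter_b = "Akt", n_draws = 100, seed = 1,
                                detrend_window = 120) {
  df <- split_pair(traces, reporter_a, reporter_b)
  cells <- unique(df$cell_id)
  if (length(cells) < 2) abort("random pairing needs at least 2 cells")
  if (n_draws == 0) {
    return(tibble(draw = integer(), cell_a = character(),
                  cell_b = character(), r = numeric()))
  }
  set.seed(as.integer(seed))
  ia <- sample.int(length(cells), n_draws, replace = TRUE)
  jb <- vapply(ia, function(i) {
    sample(setdiff(seq_along(cells), i), 1L)
  }, integer(1))
  prep <- lapply(cells, function(cl) pair_matrix(df, cl, reporter_a, reporter_b))
  r <- vapply(seq_len(n_draws), function(k) {
    pa <- prep[[ia[k]]]
    pb <- prep[[jb[k]]]
    n <- min(length(pa$a), length(pb$b))
    a <- pa$a[seq_len(n)]
    b <- pb$b[seq_len(n)]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 20) return(NA_real_)
    dt <- median(diff(pa$time))
    cell_correlation(detrend_trace(a[ok], dt, detrend_window),
                     detrend_trace(b[ok], dt, detrend_window))
  }, numeric(1))
  tibble(draw = seq_len(n_draws), cell_a = cells[ia], cell_b = cells[jb],
         r = r)
}

#' Phase shift between two oscillatory channels of one cell
#'
#' Estimates the oscillation period from detected pulses in each channel
#' (mean peak-to-peak spacing, averaged across the two channels), then finds
#' the lag maximizing the cross-correlation of the detrended series over lags
#' within 1.5 periods, refines it by parabolic interpolation around the
#' discrete maximum, and folds the lag into `[0, 0.5]` cycles. Cross-
#' correlation cannot distinguish lead from lag beyond half a cycle for
#' near-periodic signals, so only the folded magnitude is reported.
#'
#' @param time time vector in minutes.
#' @param a,b two channel value vectors on the grid.
#' @param smooth_span,window,f_hi,f_lo,min_amp pulse-detection settings used
#'   for the period estimate (see [detect_pulses()]).
#' @param detrend_window detrending window in minutes.
#' @return one-row tibble: `period_min`, `shift_cycles` (in `[0, 0.5]`),
#'   `r_at_best_lag`.
#' @export
phase_shift <- function(time, a, b, smooth_span = 3, window = 40,
                        f_hi = 0.7, f_lo = 0.3, min_amp = NULL,
                        detrend_window = 120) {
  ok <- !is.na(a) & !is.na(b)
  time <- time[ok]
  a <- a[ok]
  b <- b[ok]
  dt <- median(diff(time))
  ma_a <- if (is.null(min_amp)) 4 * noise_scale(a) else min_amp
  ma_b <- if (is.null(min_amp)) 4 * noise_scale(b) else min_amp
  pa <- detect_pulses(time, smooth_trace(a, smooth_span), window, f_hi, f_lo,
                      ma_a)
  pb <- detect_pulses(time, smooth_trace(b, smooth_span), window, f_hi, f_lo,
                      ma_b)
  if (!classify_oscillatory(pa) || !classify_oscillatory(pb)) {
    abort("phase_shift requires both channels to be oscillatory")
  }
  period <- mean(c(mean_period(pa), mean_period(pb)))
  da <- detrend_trace(a, dt, detrend_window)
  db <- detrend_trace(b, dt, detrend_window)
  lag_max <- ceiling(1.5 * period / dt)
  cc <- ccf(da, db, lag.max = lag_max, plot = FALSE)
  acf <- as.numeric(cc$acf)
  lags <- as.numeric(cc$lag)
  i <- which.max(acf)
  lag_hat <- lags[i]
  if (i > 1 && i < length(acf)) {
    y1 <- acf[i - 1]; y2 <- acf[i]; y3 <- acf[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      lag_hat <- lags[i] + 0.5 * (y1 - y3) / den
    }
  }
  shift <- abs(lag_hat * dt) / period
  shift <- shift %% 1
  shift <- min(shift, 1 - shift)
  tibble(period_min = period, shift_cycles = shift, r_at_best_lag = acf[i])
}

#' Per-cell phase shifts for a dual-reporter population
#'
#' Applies [phase_shift()] to every cell carrying both reporters;
#' non-oscillatory cells yield `NA` rows.
#'
#' @inheritParams correlation_by_cell
#' @param ... passed to [phase_shift()].
#' @return tibble with `cell_id`, `period_min`, `shift_cycles`,
#'   `r_at_best_lag`.
#' @export
phase_table <- function(traces, reporter_a = "Akt", reporter_b = "AMPK", ...) {
  df <- split_pair(traces, reporter_a, reporter_b)
  cells <- unique(df$cell_id)
  rows <- lapply(cells, function(cl) {
    p <- pair_matrix(df, cl, reporter_a, reporter_b)
    res <- tryCatch(phase_shift(p$time, p$a, p$b, ...),
                    error = function(e) tibble(period_min = NA_real_,
                                               shift_cycles = NA_real_,
                                               r_at_best_lag = NA_real_))
    dplyr::bind_cols(tibble(cell_id = cl), res)
  })
  bind_rows(rows)
}

#' Test 1:1 phase locking between two pulse trains
#'
#' Two oscillating channels of one cell are phase-locked when their cycles
#' correspond one-to-one with a stable relative offset: (a) pulse counts
#' agree within `count_tol`; (b) at least `match_frac` of the A-peaks have a
#' nearest-B-peak lag within `tol_frac` of a period of the cell's consensus
#' offset; and (c) the matched lags have small circular dispersion (circular
#' standard deviation below `lag_sd_frac` of a period). Lags are treated
#' circularly (angles `2 * pi * lag / period`, deviations measured from the
#' circular mean) so that a stable anti-phase relationship, whose raw
#' nearest-peak lags flip sign between plus and minus half a period, still
#' registers as locked.
#'
#' @param pulses_a,pulses_b pulse tibbles from [detect_pulses()] for the two
#'   channels of one cell (each with at least 5 pulses).
#' @param tol_frac nearest-peak proximity bound, fraction of a period.
#' @param count_tol allowed relative difference in pulse counts.
#' @param match_frac required fraction of proximate matches.
#' @param lag_sd_frac circular lag-dispersion bound, fraction of a period.
#' @return logical flag.
#' @export
is_phase_locked <- function(pulses_a, pulses_b, tol_frac = 0.5,
                            count_tol = 0.1, match_frac = 0.9,
                            lag_sd_frac = 0.15) {
  na <- nrow(pulses_a)
  nb <- nrow(pulses_b)
  if (na < 5 || nb < 5) abort("phase locking needs at least 5 pulses per channel")
  period <- mean(c(mean_period(pulses_a), mean_period(pulses_b)))
  if (abs(na - nb) > count_tol * max(na, nb)) return(FALSE)
  ta <- pulses_a$peak_time
  tb <- pulses_b$peak_time
  lags <- vapply(ta, function(t) tb[which.min(abs(tb - t))] - t, numeric(1))
  theta <- 2 * pi * lags / period
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  dev <- abs(atan2(sin(theta - mu), cos(theta - mu))) / (2 * pi) # cycles
  if (mean(dev <= tol_frac) < match_frac) return(FALSE)
  rbar <- min(1, sqrt(mean(cos(theta))^2 + mean(sin(theta))^2))
  circ_sd_cycles <- sqrt(pmax(0, -2 * log(rbar))) / (2 * pi)
  circ_sd_cycles < lag_sd_frac
}

#' Fraction of phase-locked cells in a dual-reporter population
#'
#' Runs pulse detection on both channels of every cell, keeps cells with at
#' least 5 pulses in each (evaluable cells), and reports the fraction
#' classified locked by [is_phase_locked()].
#'
#' @inheritParams correlation_by_cell
#' @param smooth_span,window,f_hi,f_lo,min_amp pulse-detection settings.
#' @param ... passed to [is_phase_locked()].
#' @return list with `fraction`, `n_evaluable`, `n_locked` and the per-cell
#'   tibble `cells`.
#' @export
locking_fraction <- function(traces, reporter_a = "Akt", reporter_b = "AMPK",
                             smooth_span = 3, window = 40, f_hi = 0.7,
                             f_lo = 0.3, min_amp = NULL, ...) {
  df <- split_pair(traces, reporter_a, reporter_b)
  cells <- unique(df$cell_id)
  if (length(cells) == 0L) abort("no cells carry both reporters")
  rows <- lapply(cells, function(cl) {
    p <- pair_matrix(df, cl, reporter_a, reporter_b)
    ok <- !is.na(p$a) & !is.na(p$b)
    t <- p$time[ok]
    ma_a <- if (is.null(min_amp)) 4 * noise_scale(p$a[ok]) else min_amp
    ma_b <- if (is.null(min_amp)) 4 * noise_scale(p$b[ok]) else min_amp
    pa <- detect_pulses(t, smooth_trace(p$a[ok], smooth_span), window,
                        f_hi, f_lo, ma_a)
    pb <- detect_pulses(t, smooth_trace(p$b[ok], smooth_span), window,
                        f_hi, f_lo, ma_b)
    evaluable <- nrow(pa) >= 5 && nrow(pb) >= 5
    locked <- if (evaluable) is_phase_locked(pa, pb, ...) else NA
    tibble(cell_id = cl, n_pulses_a = nrow(pa), n_pulses_b = nrow(pb),
           evaluable = evaluable, locked = locked)
  })
  cells_tbl <- bind_rows(rows)
  ev <- cells_tbl[cells_tbl$evaluable, ]
  if (nrow(ev) == 0L) abort("no evaluable cells (need >= 5 pulses per channel)")
  list(fraction = mean(ev$locked), n_evaluable = nrow(ev),
       n_locked = sum(ev$locked), cells = cells_tbl)
}
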