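#' Preset parameter tables for the synthetic trace generator
#'
#' Each preset pins the kinetic parameters of one experimental condition:
#' iodoacetate (IA) doses that drive fast glycolytic AMPK oscillations,
#' oligomycin at different glucose concentrations (initial pulse, adaptation,
#' slow recurring pulses), CCCP (sustained plateau), growth-factor baseline
#' conditions (sparse spontaneous AMPK pulses mirrored by Akt dips), a
#' dual-reporter IA condition with phase-locked NADH/Akt/AMPK oscillations,
#' and a cell-cycle condition with a geminin (GMNN) channel.
#'
#' @keywords internal
preset_table <- function() {
  list(
    ia_high  = list(family = "ia", period_mean = 18, period_cv = 0.05,
                    osc_fraction = 1.0, death_window = c(720, 1440)),
    ia_mid   = list(family = "ia", period_mean = 24, period_cv = 0.05,
                    osc_fraction = 0.97, death_window = c(720, 1440),
                    osc_death_window = c(1200, 1440)),
    ia_low5  = list(family = "ia", period_mean = 30, period_cv = 0.05,
                    osc_fraction = 0.55, death_window = c(720, 1440)),
    ia_sub   = list(family = "ia", period_mean = 30, period_cv = 0.05,
                    osc_fraction = 0, death_window = NULL),
    oligo_glc17  = list(family = "oligo", adapt_fraction = 0.85,
                        recur_period = 150, recur_jitter_sd = 25,
                        recur_walk_sd = 10, recur_amplitude = 1.0,
                        recur_duration = c(60, 150)),
    oligo_glc3.4 = list(family = "oligo", adapt_fraction = 0.20,
                        recur_period = 150, recur_jitter_sd = 25,
                        recur_walk_sd = 10, recur_amplitude = 0.5,
                        recur_duration = c(120, 240)),
    oligo_glc1.7 = list(family = "oligo", adapt_fraction = 0.07,
                        recur_period = 150, recur_jitter_sd = 25,
                        recur_walk_sd = 10, recur_amplitude = 0.5,
                        recur_duration = c(120, 240)),
    oligo_glc0   = list(family = "oligo", adapt_fraction = 0,
                        recur_amplitude = 0, baseline_level = 0.5,
                        death_window = c(300, 720)),
    cccp = list(family = "cccp", rise_half_time = 30),
    baseline_noGF        = list(family = "baseline", rate_per_10hr = 1.2,
                                treatment_time = 0),
    baseline_EGF         = list(family = "baseline", rate_per_10hr = 1.0,
                                treatment_time = 0),
    baseline_insulin     = list(family = "baseline", rate_per_10hr = 0.3,
                                treatment_time = 0),
    baseline_EGF_insulin = list(family = "baseline", rate_per_10hr = 0.25,
                                treatment_time = 0),
    dual_ia = list(family = "dual", period_mean = 24, period_cv = 0.05,
                   locked_fraction = 0.95,
                   phase_lags = c(NADH = 0, Akt = 0.25, AMPK = 0.75),
                   death_window = c(720, 1440)),
    cellcycle_EGF = list(family = "cellcycle", rate_pre_10hr = 2.0,
                         rate_post_10hr = 1.0, induction_window = c(300, 900),
                         treatment_time = 0)
  )
}

#' Available generator presets
#' @return character vector of preset names accepted by [generator_spec()].
#' @export
preset_names <- function() names(preset_table())

#' Build a validated generator specification
#'
#' Assembles the full parameter set for one synthetic trace population:
#' preset-pinned kinetics plus sampling, noise and population-size settings.
#' Any preset parameter can be overridden through `...`.
#'
#' @param preset one of [preset_names()].
#' @param n_cells number of cells to simulate.
#' @param seed integer seed; identical spec + seed reproduces identical traces.
#' @param duration total recording length in minutes.
#' @param dt sampling interval in minutes.
#' @param treatment_time treatment addition time in minutes (ignored by
#'   baseline and cell-cycle presets, which carry no acute perturbation).
#' @param pulse_amplitude nominal pulse amplitude in index units.
#' @param noise_sd standard deviation of additive Gaussian measurement noise.
#' @param drift_sd per-sample standard deviation of the random-walk drift.
#' @param ... preset parameter overrides (e.g. `osc_fraction`, `period_mean`,
#'   `death_window`, `locked_fraction`).
#'
#' @return an object of class `generator_spec`.
#' @examples
#' generator_spec("ia_high", n_cells = 10, seed = 1)
#' @export
generator_spec <- function(preset, n_cells = 50, seed = 1,
                           duration = 1440, dt = 3, treatment_time = 120,
                           pulse_amplitude = 1.0, noise_sd = 0.05,
                           drift_sd = 0.002, ...) {
  presets <- preset_table()
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(presets)) {
    abort(paste0("unknown preset '", as.character(preset)[1],
                 "'; see preset_names()"))
  }
  spec <- presets[[preset]]
  spec$preset <- preset
  spec$n_cells <- n_cells
  spec$seed <- as.integer(seed)
  spec$duration <- duration
  spec$dt <- dt
  if (is.null(spec$treatment_time)) spec$treatment_time <- treatment_time
  spec$pulse_amplitude <- pulse_amplitude
  spec$noise_sd <- noise_sd
  spec$drift_sd <- drift_sd
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  if (!is.numeric(spec$n_cells) || spec$n_cells < 0 ||
      spec$n_cells != round(spec$n_cells)) {
    abort("n_cells must be a non-negative integer")
  }
  if (spec$dt <= 0) abort("dt must be positive")
  if (spec$duration < spec$treatment_time) {
    abort("duration must be at least treatment_time")
  }
  for (f in c("osc_fraction", "adapt_fraction", "locked_fraction")) {
    if (!is.null(spec[[f]]) && (spec[[f]] < 0 || spec[[f]] > 1)) {
      abort(paste(f, "must lie in [0, 1]"))
    }
  }
  if (!is.null(spec$period_mean) && spec$period_mean <= 2 * spec$dt) {
    abort("period_mean must exceed 2 * dt to be resolvable")
  }
  invisible(spec)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec> preset:", x$preset,
      " n_cells:", x$n_cells, " seed:", x$seed, "\n")
  cat("  duration:", x$duration, "min  dt:", x$dt,
      "min  treatment at", x$treatment_time, "min\n")
  invisible(x)
}

# Per-cell RNG substream: deterministic in (seed, cell index), independent of
# population order, kept below 2^31.
cell_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 7919) %% 2147483647
}

new_trace_tbl <- function(df, spec = NULL, provenance = NULL) {
  out <- as_tibble(df)
  attr(out, "spec") <- spec
  attr(out, "provenance") <- provenance
  class(out) <- c("trace_tbl", class(out))
  out
}

#' Simulate a synthetic single-cell trace population
#'
#' Draws per-cell kinetic parameters (period, oscillatory / adapting flags,
#' death time, event times) from seeded per-cell substreams and renders each
#' cell's reporter waveform as a baseline plus a train of raised-cosine pulses
#' ([pulse_waveform()]), with additive Gaussian measurement noise and a
#' Gaussian random-walk drift. Values after a cell's death time are `NA`.
#'
#' @param spec a [generator_spec()], or a preset name (in which case the
#'   remaining arguments are forwarded to [generator_spec()]).
#' @param ... passed to [generator_spec()] when `spec` is a preset name.
#'
#' @return a `trace_tbl`: a long tibble with columns `cell_id`, `time_min`,
#'   `reporter`, `value`, `condition`, `replicate`, `treatment_time_min`,
#'   carrying the spec and a per-cell provenance table (realized period,
#'   oscillatory/adapting/locked flags, death and induction times) as
#'   attributes.
#' @examples
#' tr <- simulate_traces("ia_high", n_cells = 3, seed = 1)
#' dplyr::count(tr, cell_id)
#' @export
simulate_traces <- function(spec, ...) {
  if (is.character(spec)) spec <- generator_spec(spec, ...)
  stopifnot(inherits(spec, "generator_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  sim_fun <- switch(spec$family,
    ia = sim_cell_ia, oligo = sim_cell_oligo, cccp = sim_cell_cccp,
    baseline = sim_cell_baseline, dual = sim_cell_dual,
    cellcycle = sim_cell_cellcycle,
    abort(paste("no simulator for preset family", spec$family)))

  cells <- vector("list", spec$n_cells)
  prov <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    set.seed(cell_seed(spec$seed, i))
    cell <- sim_fun(spec, times)
    id <- sprintf("cell_%04d", i)
    chans <- names(cell$values)
    cells[[i]] <- tibble(
      cell_id = id,
      time_min = rep(times, times = length(chans)),
      reporter = rep(chans, each = length(times)),
      value = unlist(cell$values, use.names = FALSE),
      condition = spec$preset,
      replicate = "R1",
      treatment_time_min = spec$treatment_time
    )
    prov[[i]] <- as_tibble(c(list(cell_id = id), cell$prov))
  }
  df <- if (spec$n_cells > 0) bind_rows(cells) else tibble(
    cell_id = character(), time_min = numeric(), reporter = character(),
    value = numeric(), condition = character(), replicate = character(),
    treatment_time_min = numeric())
  prov_df <- if (spec$n_cells > 0) bind_rows(prov) else tibble(cell_id = character())
  new_trace_tbl(df, spec = spec, provenance = prov_df)
}

#' Per-cell provenance of a simulated trace set
#' @param traces a `trace_tbl` produced by [simulate_traces()].
#' @return tibble of realized per-cell parameters.
#' @export
trace_provenance <- function(traces) {
  p <- attr(traces, "provenance")
  if (is.null(p)) abort("traces carry no provenance (not simulated?)")
  p
}

# ---- shared helpers ---------------------------------------------------------

finish_channel <- function(waveform, times, spec, death_time = NULL,
                           noise_sd = spec$noise_sd) {
  n <- length(times)
  v <- waveform + rnorm(n, 0, noise_sd) + cumsum(rnorm(n, 0, spec$drift_sd))
  if (!is.null(death_time) && is.finite(death_time)) {
    v[times > death_time] <- NA_real_
  }
  v
}

draw_death <- function(spec, window) {
  if (is.null(window)) return(Inf)
  spec$treatment_time + runif(1, window[1], window[2])
}

# Oscillation event train: centers at phase0 + k * period from treatment on,
# amplitudes jittered per event.
osc_events <- function(spec, period, t_end, phase0 = NULL,
                       amplitude = spec$pulse_amplitude,
                       duty = 0.7, extra_offset = 0, walk_sd = 0) {
  if (is.null(phase0)) phase0 <- runif(1, 0.25, 0.75) * period
  first <- spec$treatment_time + phase0
  if (first > t_end) return(NULL)
  k <- 0:floor((t_end - first) / period)
  centers <- first + k * period + extra_offset
  if (walk_sd > 0 && length(k) > 1) {
    centers <- centers + cumsum(c(0, rnorm(length(k) - 1, 0, walk_sd)))
  }
  data.frame(center = centers,
             amplitude = amplitude * runif(length(centers), 0.9, 1.1),
             duration = duty * period)
}

# ---- preset families --------------------------------------------------------

sim_cell_ia <- function(spec, times) {
  oscillatory <- runif(1) < spec$osc_fraction
  period <- max(2.1 * spec$dt,
                rnorm(1, spec$period_mean, spec$period_cv * spec$period_mean))
  dw <- if (oscillatory && !is.null(spec$osc_death_window)) {
    spec$osc_death_window
  } else spec$death_window
  death <- draw_death(spec, dw)
  t_end <- min(death, spec$duration)
  if (oscillatory) {
    ev <- osc_events(spec, period, t_end)
    wf <- pulse_waveform(times, ev, baseline = 0)
  } else {
    # sub-oscillatory cells show a modest sustained elevation, no pulses
    wf <- logistic_rise(times, spec$treatment_time, 0.4 * spec$pulse_amplitude)
  }
  list(values = list(AMPK = finish_channel(wf, times, spec, death)),
       prov = list(oscillatory = oscillatory, period_min = period,
                   death_time_min = death))
}

sim_cell_oligo <- function(spec, times) {
  adapting <- runif(1) < spec$adapt_fraction
  death <- draw_death(spec, spec$death_window)
  t_end <- min(death, spec$duration)
  baseline <- spec$baseline_level %||% 0
  amp0 <- spec$pulse_amplitude * runif(1, 0.9, 1.1)
  center0 <- spec$treatment_time + 40
  if (spec$recur_amplitude == 0 && !adapting && !is.null(spec$death_window)) {
    # glucose-starved: high baseline, small sustained rise, early death
    wf <- baseline + logistic_rise(times, spec$treatment_time,
                                   0.3 * spec$pulse_amplitude)
  } else if (adapting) {
    init <- data.frame(center = center0, amplitude = amp0, duration = 80)
    wf <- baseline + pulse_waveform(times, init, baseline = 0)
  } else {
    # partial adaptation: rise like the initial pulse, settle at 60% amplitude
    wf <- rep(baseline, length(times))
    rise <- times >= center0 - 40 & times <= center0
    wf[rise] <- wf[rise] +
      amp0 * 0.5 * (1 - cos(2 * pi * (times[rise] - center0 + 40) / 80))
    fall <- times > center0 & times <= center0 + 40
    wf[fall] <- wf[fall] + 0.6 * amp0 +
      0.4 * amp0 * cos(pi * (times[fall] - center0) / 80)^2
    wf[times > center0 + 40] <- wf[times > center0 + 40] + 0.6 * amp0
  }
  if (!is.null(spec$recur_period) && spec$recur_amplitude > 0) {
    k_max <- floor((t_end - center0) / spec$recur_period)
    if (k_max >= 1) {
      k <- seq_len(k_max)
      jit <- ifelse(k <= 2, 0, rnorm(length(k), 0, spec$recur_jitter_sd))
      walk <- cumsum(c(0, 0, rnorm(max(0, length(k) - 2), 0,
                                   spec$recur_walk_sd))[seq_along(k)])
      recur_amp <- spec$recur_amplitude * (if (adapting) 1 else 0.5)
      ev <- data.frame(
        center = center0 + k * spec$recur_period + jit + walk,
        amplitude = recur_amp * runif(length(k), 0.85, 1.15),
        duration = runif(length(k), spec$recur_duration[1],
                         spec$recur_duration[2]))
      wf <- wf + pulse_waveform(times, ev, baseline = 0)
    }
  }
  list(values = list(AMPK = finish_channel(wf, times, spec, death)),
       prov = list(adapting = adapting, death_time_min = death))
}

sim_cell_cccp <- function(spec, times) {
  amp <- spec$pulse_amplitude * runif(1, 0.9, 1.1)
  wf <- logistic_rise(times, spec$treatment_time, amp,
                      half_time = spec$rise_half_time)
  list(values = list(AMPK = finish_channel(wf, times, spec)),
       prov = list(plateau = amp, death_time_min = Inf))
}

sim_cell_baseline <- function(spec, times) {
  dur <- spec$duration
  n_ev <- rpois(1, spec$rate_per_10hr * dur / 600)
  ev <- NULL
  if (n_ev > 0) {
    ev <- data.frame(center = sort(runif(n_ev, 0, dur)),
                     amplitude = 0.5 * spec$pulse_amplitude *
                       runif(n_ev, 0.85, 1.15),
                     duration = runif(n_ev, 40, 80))
  }
  ampk <- pulse_waveform(times, ev, baseline = 0)
  akt_ev <- ev
  if (!is.null(akt_ev)) akt_ev$amplitude <- -0.8 * akt_ev$amplitude
  akt <- pulse_waveform(times, akt_ev, baseline = 1)
  list(values = list(AMPK = finish_channel(ampk, times, spec),
                     Akt = finish_channel(akt, times, spec)),
       prov = list(n_events = n_ev, death_time_min = Inf))
}

sim_cell_dual <- function(spec, times) {
  locked <- runif(1) < spec$locked_fraction
  period <- max(2.1 * spec$dt,
                rnorm(1, spec$period_mean, spec$period_cv * spec$period_mean))
  death <- draw_death(spec, spec$death_window)
  t_end <- min(death, spec$duration)
  lags <- spec$phase_lags
  phase0 <- runif(1, 0.25, 0.75) * period
  values <- list()
  for (ch in names(lags)) {
    if (locked) {
      ev <- osc_events(spec, period, t_end, phase0 = phase0,
                       extra_offset = lags[[ch]] * period)
    } else {
      # independent phase origin and per-cycle phase diffusion per channel
      ev <- osc_events(spec, period, t_end, phase0 = runif(1, 0, period),
                       walk_sd = 0.08 * period)
    }
    base <- if (ch == "AMPK") 0 else 1
    values[[ch]] <- finish_channel(pulse_waveform(times, ev, baseline = base),
                                   times, spec, death)
  }
  list(values = values,
       prov = list(locked = locked, period_min = period,
                   death_time_min = death))
}

sim_cell_cellcycle <- function(spec, times) {
  t_ind <- runif(1, spec$induction_window[1], spec$induction_window[2])
  n_pre <- rpois(1, spec$rate_pre_10hr * t_ind / 600)
  n_post <- rpois(1, spec$rate_post_10hr * (spec$duration - t_ind) / 600)
  centers <- sort(c(runif(n_pre, 0, t_ind),
                    runif(n_post, t_ind, spec$duration)))
  ev <- NULL
  if (length(centers) > 0) {
    ev <- data.frame(center = centers,
                     amplitude = 0.5 * spec$pulse_amplitude *
                       runif(length(centers), 0.85, 1.15),
                     duration = runif(length(centers), 40, 80))
  }
  ampk <- pulse_waveform(times, ev, baseline = 0)
  gmnn <- pmin(1, pmax(0, (times - t_ind) / 240))
  list(values = list(
         AMPK = finish_channel(ampk, times, spec),
         GMNN = finish_channel(gmnn, times, spec,
                               noise_sd = 0.4 * spec$noise_sd)),
       prov = list(induction_time_min = t_ind, n_events = length(centers),
                   death_time_min = Inf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
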