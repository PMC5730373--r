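#' Raised-cosine pulse waveform
#'
#' Evaluates a baseline plus a train of raised-cosine pulse events on a time
#' grid. Each event contributes `A * w((t - start) / d)` with
#' `w(u) = 0.5 * (1 - cos(2 * pi * u))` for `u` in `[0, 1]` and 0 elsewhere,
#' where `start = center - d / 2`, so the kernel peaks at the event center
#' with value `A` and integrates to `A * d / 2` over its support. Overlapping
#' events sum. Negative amplitudes are allowed (inverted dips, e.g. Akt
#' translocation responses mirrored against AMPK pulses).
#'
#' @param times numeric vector of time points (minutes).
#' @param events data frame with columns `center`, `amplitude`, `duration`
#'   (minutes), one row per pulse event. Zero rows give the bare baseline.
#' @param baseline scalar baseline value (index units).
#'
#' @return numeric vector of waveform values, same length as `times`.
#' @examples
#' t <- seq(0, 60, by = 1)
#' ev <- data.frame(center = 30, amplitude = 1, duration = 20)
#' y <- pulse_waveform(t, ev, baseline = 0.1)
#' max(y) # baseline + amplitude at the event center
#' @export
pulse_waveform <- function(times, events, baseline = 0) {
  stopifnot(is.numeric(times))
  if (is.null(events) || nrow(events) == 0L) {
    return(rep(baseline, length(times)))
  }
  events <- as.data.frame(events)
  req <- c("center", "amplitude", "duration")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0L) {
    abort(paste0("events is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(events$duration)) || any(events$duration <= 0)) {
    abort("event durations must be positive and finite")
  }
  out <- rep(baseline, length(times))
  for (k in seq_len(nrow(events))) {
    start <- events$center[k] - events$duration[k] / 2
    u <- (times - start) / events$duration[k]
    inside <- u >= 0 & u <= 1
    if (any(inside)) {
      out[inside] <- out[inside] +
        events$amplitude[k] * 0.5 * (1 - cos(2 * pi * u[inside]))
    }
  }
  out
}

# Logistic rise used for sustained (non-pulsatile) responses: 0 before
# treatment, approaching `amplitude` with the given half-time after it.
logistic_rise <- function(times, onset, amplitude, half_time = 30, tau = 8) {
  out <- numeric(length(times))
  post <- times >= onset
  out[post] <- amplitude / (1 + exp(-((times[post] - onset) - half_time) / tau))
  out
}
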