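# Brute-force pulse-detection oracle, independent of the package's state
# machine: computes the local-range cutoffs directly, lists every interval
# between consecutive below-lower-cutoff samples, and emits a pulse for each
# interval containing an above-upper-cutoff sample.
oracle_detect <- function(time, value, window = 40, f_hi = 0.7, f_lo = 0.3,
                          min_amp = 0) {
  n <- length(value)
  dt <- stats::median(diff(time))
  hw <- max(1, round(window / (2 * dt)))
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    w <- value[max(1, i - hw):min(n, i + hw)]
    lo[i] <- min(w) + f_lo * (max(w) - min(w))
    hi[i] <- min(w) + f_hi * (max(w) - min(w))
  }
  below <- which(value < lo)
  out <- data.frame(peak_time = numeric(0), peak_value = numeric(0),
                    baseline_value = numeric(0), amplitude = numeric(0),
                    start_time = numeric(0), end_time = numeric(0))
  if (length(below) < 2) return(out)
  prev_end <- 1
  for (k in seq_len(length(below) - 1)) {
    b1 <- below[k]
    b2 <- below[k + 1]
    if (b2 - b1 < 2) next
    inside <- (b1 + 1):(b2 - 1)
    if (!any(value[inside] > hi[inside])) next
    seg <- b1:b2
    peak <- seg[which.max(value[seg])]
    baseline <- min(value[prev_end:peak])
    amp <- value[peak] - baseline
    prev_end <- b2
    if (amp < min_amp) next
    out <- rbind(out, data.frame(
      peak_time = time[peak], peak_value = value[peak],
      baseline_value = baseline, amplitude = amp,
      start_time = time[b1], end_time = time[b2]))
  }
  out
}

# Periodic triangle wave on a uniform grid.
triangle_wave <- function(times, period, amplitude = 1) {
  ph <- (times %% period) / period
  amplitude * (1 - 2 * abs(ph - 0.5))
}
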