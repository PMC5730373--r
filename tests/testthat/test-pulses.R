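test_that("smoothing is the identity at span 1 and preserves constants", {
  x <- rnorm(50)
  expect_identical(smooth_trace(x, 1), x)
  expect_equal(smooth_trace(rep(2, 30), 7), rep(2, 30))
})

test_that("smoothing shrinks white-noise sd by about sqrt(span)", {
  set.seed(101)
  k <- 5
  reps <- 200
  sds <- replicate(reps, {
    x <- rnorm(200)
    sd(smooth_trace(x, k)[20:180])
  })
  # interior points average k independent samples -> sd ~ 1/sqrt(k)
  se <- sd(sds) / sqrt(reps)
  expect_lt(abs(mean(sds) - 1 / sqrt(k)), 3 * se + 0.01)
})

test_that("detector finds no pulses in constant or too-short traces", {
  t <- seq(0, 300, by = 3)
  expect_equal(nrow(detect_pulses(t, rep(1, length(t)))), 0)
  expect_warning(p <- detect_pulses(seq(0, 30, 3), rep(c(0, 1), length.out = 11),
                                    window = 120),
                 "shorter")
  expect_equal(nrow(p), 0)
})

test_that("detector matches the brute-force oracle exactly", {
  t <- seq(0, by = 3, length.out = 200)
  cases <- list(
    triangle = triangle_wave(t, period = 30),
    skewed = triangle_wave(t, period = 48, amplitude = 2) +
      0.3 * sin(2 * pi * t / 200),
    noisy = {
      set.seed(7)
      triangle_wave(t, period = 60) + rnorm(length(t), 0, 0.05)
    },
    drifting = {
      set.seed(8)
      triangle_wave(t, period = 36) + cumsum(rnorm(length(t), 0, 0.01))
    })
  for (nm in names(cases)) {
    x <- cases[[nm]]
    got <- detect_pulses(t, x, min_amp = 0.2)
    want <- oracle_detect(t, x, min_amp = 0.2)
    expect_equal(got$peak_time, want$peak_time, info = nm)
    expect_equal(got$amplitude, want$amplitude, info = nm)
    expect_equal(got$baseline_value, want$baseline_value, info = nm)
    expect_equal(got$start_time, want$start_time, info = nm)
    expect_equal(got$end_time, want$end_time, info = nm)
  }
})

test_that("detection is offset-invariant and scale-equivariant", {
  set.seed(21)
  t <- seq(0, by = 3, length.out = 300)
  x <- triangle_wave(t, period = 45) + rnorm(length(t), 0, 0.04)
  base <- detect_pulses(t, x, min_amp = 0.2)
  shifted <- detect_pulses(t, x + 5, min_amp = 0.2)
  expect_equal(base$peak_time, shifted$peak_time)
  expect_equal(base$amplitude, shifted$amplitude)
  scaled <- detect_pulses(t, 3 * x, min_amp = 3 * 0.2)
  expect_equal(base$peak_time, scaled$peak_time)
  expect_equal(3 * base$amplitude, scaled$amplitude)
  # pulse score scales with the trace
  expect_equal(3 * pulse_score(base, max(t)),
               pulse_score(scaled, max(t)))
})

test_that("pulse score is amplitude-sum per hour", {
  p <- tibble::tibble(amplitude = c(0.5, 1.0))
  expect_equal(pulse_score(p, 300), 0.3)
  expect_equal(pulse_score(p[0, ], 300), 0)
  expect_error(pulse_score(p, 0), "positive")
})

test_that("mean period needs five pulses and averages peak spacing", {
  p <- tibble::tibble(peak_time = c(0, 10, 20, 30, 40))
  expect_equal(mean_period(p), 10)
  expect_true(is.na(mean_period(p[1:4, ])))
})

test_that("longest run counts pulses, breaks on wide gaps", {
  mk <- function(spacings) tibble::tibble(peak_time = cumsum(c(0, spacings)))
  expect_equal(longest_pulse_run(mk(c(30, 30, 30, 30))), 5L)
  expect_equal(longest_pulse_run(mk(c(30, 30, 30, 30, 120, 30))), 5L)
  expect_equal(longest_pulse_run(mk(numeric(0))), 1L)
  expect_equal(longest_pulse_run(tibble::tibble(peak_time = numeric(0))), 0L)
  expect_false(classify_oscillatory(mk(c(30, 30, 30))))
  expect_true(classify_oscillatory(mk(c(30, 30, 30, 30))))
})

test_that("adding a pulse inside a qualifying run never breaks the call", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    times <- cumsum(c(0, runif(n - 1, 10, 55)))
    p <- tibble::tibble(peak_time = times)
    stopifnot(classify_oscillatory(p))
    extra <- runif(1, min(times), max(times))
    p2 <- tibble::tibble(peak_time = sort(c(times, extra)))
    expect_true(classify_oscillatory(p2))
  }
})

test_that("time to baseline matches the analytic crossing of a known decay", {
  dt <- 1
  t <- seq(0, 600, by = dt)
  treatment <- 120
  tau <- 60
  A <- 1
  peak_t <- treatment + 40
  x <- ifelse(t <= peak_t,
              ifelse(t > treatment, A * (t - treatment) / 40, 0),
              A * exp(-(t - peak_t) / tau))
  got <- time_to_baseline(t, x, treatment, smooth_span = 1)
  # solve A * exp(-(t - peak)/tau) = 0.25 * A
  analytic <- (peak_t + tau * log(4)) - treatment
  expect_lt(abs(got - analytic), 2 * dt)
})

test_that("plateaus never return to baseline; flat traces return immediately", {
  tr <- simulate_traces("cccp", n_cells = 4, seed = 2)
  for (cl in unique(tr$cell_id)) {
    d <- tr[tr$cell_id == cl, ]
    expect_true(is.na(time_to_baseline(d$time_min, d$value, 120)))
  }
  set.seed(5)
  t <- seq(0, 600, by = 3)
  flat <- rnorm(length(t), 0, 0.02)
  expect_lt(time_to_baseline(t, flat, 120), 60)
})

test_that("adaptation fraction is 1 for flat populations and errors when empty", {
  flat <- do.call(rbind, lapply(1:5, function(i) {
    tibble::tibble(cell_id = paste0("c", i), time_min = seq(0, 600, 3),
                   reporter = "AMPK",
                   value = rep(0.1 * i, 201), condition = "x",
                   replicate = "R1", treatment_time_min = 120)
  }))
  expect_equal(adaptation_fraction(flat), 1)
  expect_error(adaptation_fraction(flat[flat$reporter == "nope", ]), "no traces")
})

test_that("per-cell period recovery is within 10% across oscillatory presets", {
  for (pre in c("ia_high", "ia_low5")) {
    tr <- simulate_traces(pre, n_cells = 30, seed = 13)
    s <- summarize_pulses(tr)
    target <- attr(tr, "spec")$period_mean
    est <- median(s$mean_period_min[s$oscillatory], na.rm = TRUE)
    expect_lt(abs(est - target) / target, 0.1)
  }
})
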