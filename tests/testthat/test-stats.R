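test_that("boxplot summary follows the quartile and notch conventions", {
  s <- boxplot_summary(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_lo, 1)
  expect_equal(s$whisker_hi, 9)
  s2 <- boxplot_summary(rep(4, 10))
  expect_equal(s2$q1, 4)
  expect_equal(s2$q3, 4)
  expect_equal(s2$notch_lo, 4)
  x <- 1:100
  s3 <- boxplot_summary(x)
  iqr <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  expect_equal(s3$notch_hi - s3$notch_lo, 2 * 1.57 * iqr / sqrt(100))
  expect_error(boxplot_summary(numeric(0)), "at least one")
})

test_that("whiskers stop at the last value inside 1.5 IQR fences", {
  x <- c(1:20, 100) # 100 is an outlier
  s <- boxplot_summary(x)
  expect_equal(s$whisker_hi, 20)
  expect_equal(s$whisker_lo, 1)
})

test_that("identical groups are not significant; shifted groups are", {
  set.seed(55)
  x <- rnorm(40)
  d <- data.frame(g = rep(c("a", "b"), each = 40), s = c(x, x))
  cmp <- compare_pulse_scores(d, "g", "s")
  expect_gt(glance(cmp)$p_value, 0.9)
  expect_false(tidy(cmp)$significant)
  d2 <- data.frame(g = rep(c("a", "b"), each = 50),
                   s = c(rnorm(50), rnorm(50, 2)))
  cmp2 <- compare_pulse_scores(d2, "g", "s")
  expect_lt(tidy(cmp2)$p_adj, 0.01)
  expect_error(compare_pulse_scores(data.frame(g = c("a", "a", "b"),
                                               s = 1:3), "g", "s"),
               "below minimum")
})

test_that("Bonferroni adjustment is monotone and equals raw p for one pair", {
  set.seed(56)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 20),
                  s = c(rnorm(20), rnorm(20, 0.5), rnorm(20, 1)))
  cmp <- compare_pulse_scores(d, "g", "s")
  pw <- tidy(cmp)
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 3))
  d2 <- d[d$g != "c", ]
  one <- tidy(compare_pulse_scores(d2, "g", "s"))
  expect_equal(one$p_adj, one$p_raw)
})

test_that("omnibus type-I error sits near the nominal 5% level", {
  set.seed(57)
  reps <- 1000
  rejects <- replicate(reps, {
    g <- rep(c("a", "b", "c"), each = 15)
    kruskal.test(rnorm(45), factor(g))$p.value < 0.05
  })
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rejects) - 0.05), 3 * se)
})

test_that("preset pulse-score contrasts reproduce the expected ordering", {
  mk <- function(p, seed) {
    s <- summarize_pulses(simulate_traces(p, n_cells = 30, seed = seed))
    s[s$reporter == "AMPK", c("condition", "pulse_score")]
  }
  d <- rbind(mk("oligo_glc17", 31), mk("cccp", 32), mk("ia_mid", 33))
  cmp <- compare_pulse_scores(d, "condition", "pulse_score")
  pw <- tidy(cmp)
  # pulsatile conditions beat the sustained CCCP plateau
  oc <- pw[(pw$group1 == "cccp") != (pw$group2 == "cccp"), ]
  expect_true(all(oc$significant))
  med <- tapply(d$pulse_score, d$condition, median)
  expect_gt(med[["oligo_glc17"]], med[["cccp"]])
  expect_gt(med[["ia_mid"]], med[["cccp"]])
})

test_that("GMNN induction detection finds the programmed transition", {
  tr <- simulate_traces("cellcycle_EGF", n_cells = 10, seed = 44)
  prov <- trace_provenance(tr)
  for (cl in prov$cell_id) {
    g <- tr[tr$cell_id == cl & tr$reporter == "GMNN", ]
    est <- gmnn_induction_time(g$time_min, g$value)
    expect_lt(abs(est - (prov$induction_time_min[prov$cell_id == cl] + 48)),
              30)
  }
})

test_that("cell-cycle windows score symmetric traces equally and detect rate drops", {
  # symmetric trace around a provided induction time -> identical windows
  t <- seq(0, 1200, by = 3)
  ev <- data.frame(center = c(300, 900), amplitude = 1, duration = 60)
  v <- pulse_waveform(t, ev)
  sym <- tibble::tibble(cell_id = "c1",
                        time_min = rep(t, 2),
                        reporter = rep(c("AMPK", "GMNN"), each = length(t)),
                        value = c(v, as.numeric(t >= 600)),
                        condition = "x", replicate = "R1",
                        treatment_time_min = 0)
  w <- cell_cycle_window_scores(sym, induction_times = c(c1 = 600))
  expect_equal(w$scores$pre_score, w$scores$post_score)
  expect_error(cell_cycle_window_scores(sym[sym$reporter == "AMPK", ]),
               "GMNN")
  # generator-pinned 2:1 rate drop across induction
  tr <- simulate_traces("cellcycle_EGF", n_cells = 150, seed = 45)
  res <- cell_cycle_window_scores(tr)
  g <- glance(res)
  expect_gt(g$median_pre, g$median_post)
  expect_lt(g$p_value, 0.05)
})
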