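#' Notched boxplot summary of a sample
#'
#' Quartiles by the standard linear-interpolation convention, whiskers at the
#' most extreme observations within 1.5 interquartile ranges of the box, and
#' a median notch of half-width `1.57 * IQR / sqrt(n)`; two samples whose
#' notches do not overlap differ in their medians at roughly the 5% level.
#'
#' @param values numeric vector (at least one finite value).
#' @return one-row tibble: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `notch_lo`, `notch_hi`.
#' @examples
#' boxplot_summary(1:9)
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) abort("boxplot_summary needs at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  notch <- 1.57 * iqr / sqrt(length(values))
  tibble(
    n = length(values), median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(values[values >= lo_fence]),
    whisker_hi = max(values[values <= hi_fence]),
    notch_lo = q[2] - notch, notch_hi = q[2] + notch
  )
}

#' Compare pulse-score distributions across groups
#'
#' Omnibus Kruskal-Wallis test across all groups, followed by all pairwise
#' two-group Kruskal-Wallis tests with Bonferroni correction (raw p-value
#' multiplied by the number of pairs, capped at 1). Significance flags use
#' the 0.05 level on the adjusted p-values.
#'
#' @param data data frame of per-cell scores.
#' @param group,score column names (strings) holding the group label and the
#'   score.
#' @param min_n minimum group size (default 5).
#' @return object of class `pulse_comparison` with [tidy()] (pairwise table)
#'   and [glance()] (omnibus test) methods.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10), s = c(rnorm(10), rnorm(10, 2)))
#' cmp <- compare_pulse_scores(d, group = "g", score = "s")
#' glance(cmp)
#' tidy(cmp)
#' @export
compare_pulse_scores <- function(data, group = "condition",
                                 score = "pulse_score", min_n = 5) {
  g <- factor(data[[group]])
  x <- data[[score]]
  keep <- is.finite(x)
  g <- droplevels(g[keep])
  x <- x[keep]
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least two groups")
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    abort(paste0("group(s) below minimum n=", min_n, ": ",
                 paste(small, collapse = ", ")))
  }
  omni <- kruskal.test(x, g)
  labs <- levels(g)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    sel <- g %in% pr
    kt <- kruskal.test(x[sel], droplevels(g[sel]))
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = unname(kt$statistic), p_raw = kt$p.value)
  })
  pw <- bind_rows(pw)
  pw$p_adj <- pmin(1, pw$p_raw * length(pairs))
  pw$significant <- pw$p_adj < 0.05
  structure(list(
    groups = tibble(group = labs, n = as.integer(sizes[labs])),
    H_statistic = unname(omni$statistic),
    df = unname(omni$parameter),
    p_value = omni$p.value,
    pairwise = pw,
    summaries = bind_rows(lapply(labs, function(l) {
      dplyr::bind_cols(tibble(group = l), boxplot_summary(x[g == l]))
    })),
    data = tibble(group = as.character(g), score = x)
  ), class = "pulse_comparison")
}

#' @export
print.pulse_comparison <- function(x, ...) {
  cat("<pulse_comparison>", nrow(x$groups), "groups, Kruskal-Wallis H =",
      signif(x$H_statistic, 4), ", p =", format.pval(x$p_value), "\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_pulse_scores
#' @param x a `pulse_comparison` object.
#' @param ... unused.
#' @export
tidy.pulse_comparison <- function(x, ...) x$pairwise

#' @rdname compare_pulse_scores
#' @export
glance.pulse_comparison <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), H_statistic = x$H_statistic,
         df = x$df, p_value = x$p_value)
}

#' Detect the geminin induction time of one cell
#'
#' First upward crossing of a threshold set at `frac` of the cell's maximum
#' GMNN signal; a simple operationalization of the G1-to-S transition.
#'
#' @param time,value GMNN trace vectors.
#' @param frac threshold fraction of the per-cell maximum (default 0.2).
#' @return induction time in minutes, or `NA` if the signal never crosses.
#' @export
gmnn_induction_time <- function(time, value, frac = 0.2) {
  ok <- !is.na(value)
  time <- time[ok]
  value <- value[ok]
  if (length(value) == 0L) return(NA_real_)
  thr <- frac * max(value)
  i <- which(value >= thr)
  if (length(i) == 0L || i[1] == 1L) return(NA_real_)
  time[i[1]]
}

#' Pulse scores in windows around the G1-to-S transition
#'
#' For every cell with a GMNN channel, scores AMPK pulses in a 10-hr window
#' before the GMNN induction time and a 10-hr window immediately after it
#' (windows truncated to the available recording; cells with fewer than
#' `min_side` minutes on either side are excluded), and compares the paired
#' pre/post scores with a two-sided Wilcoxon signed-rank test.
#'
#' @param traces a `trace_tbl` containing `AMPK` and `GMNN` reporters.
#' @param induction_times optional named vector (cell_id -> minutes); when
#'   absent, induction is detected with [gmnn_induction_time()].
#' @param window_min half-window length in minutes (default 600).
#' @param min_side minimum recording required on each side, minutes.
#' @param reporter scored reporter (default `"AMPK"`).
#' @param ... pulse-detection settings passed to [detect_pulses()] via
#'   [smooth_trace()] span etc. (uses defaults otherwise).
#' @return object of class `window_comparison`; [tidy()] gives per-cell
#'   paired scores, [glance()] the Wilcoxon test.
#' @export
cell_cycle_window_scores <- function(traces, induction_times = NULL,
                                     window_min = 600, min_side = 300,
                                     reporter = "AMPK", ...) {
  df <- as_tibble(traces)
  if (!"GMNN" %in% df$reporter) abort("traces carry no GMNN channel")
  cells <- unique(df$cell_id)
  rows <- lapply(cells, function(cl) {
    d <- df[df$cell_id == cl, ]
    g <- d[d$reporter == "GMNN", ]
    a <- d[d$reporter == reporter, ]
    if (nrow(g) == 0L || nrow(a) == 0L) return(NULL)
    t_ind <- if (!is.null(induction_times)) {
      unname(induction_times[cl])
    } else {
      gmnn_induction_time(g$time_min, g$value)
    }
    if (is.na(t_ind)) return(NULL)
    ok <- !is.na(a$value)
    t <- a$time_min[ok]
    v <- a$value[ok]
    left <- t_ind - max(min(t), t_ind - window_min)
    right <- min(max(t), t_ind + window_min) - t_ind
    if (left < min_side || right < min_side) return(NULL)
    ma <- 4 * noise_scale(v)
    score_window <- function(lo, hi) {
      sel <- t >= lo & t < hi
      if (sum(sel) < 3) return(NA_real_)
      p <- detect_pulses(t[sel], smooth_trace(v[sel], 3), min_amp = ma, ...)
      pulse_score(p, hi - lo)
    }
    tibble(cell_id = cl, induction_min = t_ind,
           pre_score = score_window(t_ind - left, t_ind),
           post_score = score_window(t_ind, t_ind + right))
  })
  scores <- bind_rows(rows)
  scores <- scores[is.finite(scores$pre_score) & is.finite(scores$post_score), ]
  if (nrow(scores) == 0L) abort("no cells with enough recording on both sides")
  wt <- suppressWarnings(
    wilcox.test(scores$pre_score, scores$post_score, paired = TRUE))
  structure(list(scores = scores, statistic = unname(wt$statistic),
                 p_value = wt$p.value, n = nrow(scores)),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat("<window_comparison>", x$n, "cells; median pre =",
      signif(median(x$scores$pre_score), 3), ", post =",
      signif(median(x$scores$post_score), 3),
      "; Wilcoxon p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' @rdname cell_cycle_window_scores
#' @param x a `window_comparison` object.
#' @export
tidy.window_comparison <- function(x, ...) x$scores

#' @rdname cell_cycle_window_scores
#' @export
glance.window_comparison <- function(x, ...) {
  tibble(n = x$n, statistic = x$statistic, p_value = x$p_value,
         median_pre = median(x$scores$pre_score),
         median_post = median(x$scores$post_score))
}
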