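#' Plot single-cell traces
#'
#' One panel per reporter, one line per cell, with the treatment time marked.
#'
#' @param object a `trace_tbl`.
#' @param max_cells plot at most this many cells (first by id).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trace_tbl <- function(object, max_cells = 20, ...) {
  df <- as_tibble(object)
  keep <- head(unique(df$cell_id), max_cells)
  df <- df[df$cell_id %in% keep, ]
  tt <- unique(df$treatment_time_min)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value,
                                        group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~reporter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = "index")
  if (length(tt) == 1 && is.finite(tt) && tt > 0) {
    p <- p + ggplot2::geom_vline(xintercept = tt, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Notched boxplots of pulse scores by group
#'
#' Mirrors the field's display convention: box = interquartile range, red
#' line at the median, whiskers to the most extreme values within 1.5 IQR,
#' notches marking the approximate 5% median comparison interval; outliers
#' hidden.
#'
#' @param object a `pulse_comparison` from [compare_pulse_scores()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pulse_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.shape = NA,
                          fatten = 1.2, colour = "black",
                          staplewidth = 0.3) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.74,
                          colour = "red", linewidth = 0.3) +
    ggplot2::coord_cartesian(
      ylim = c(0, 1.05 * max(object$summaries$whisker_hi))) +
    ggplot2::labs(x = NULL, y = "pulse score (index / hr)")
}

#' Plot detected pulses over a trace
#'
#' @param time,value trace vectors.
#' @param pulses pulse tibble from [detect_pulses()].
#' @return a ggplot object.
#' @export
plot_pulses <- function(time, value, pulses) {
  df <- tibble(time_min = time, value = value)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (min)", y = "index")
  if (nrow(pulses) > 0) {
    p <- p + ggplot2::geom_point(data = pulses,
                                 ggplot2::aes(.data$peak_time, .data$peak_value),
                                 colour = "red", shape = 17)
  }
  p
}

#' Histogram of per-cell correlations against the random-pairing null
#'
#' @param matched tibble from [correlation_by_cell()].
#' @param null tibble from [random_pairing_null()].
#' @return a ggplot object.
#' @export
plot_correlation_null <- function(matched, null) {
  df <- bind_rows(
    tibble(r = matched$r, set = "same cell"),
    tibble(r = null$r, set = "random pairing"))
  ggplot2::ggplot(df[is.finite(df$r), ], ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            fill = "grey60", colour = "grey20") +
    ggplot2::facet_wrap(~set, ncol = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "correlation (detrended)", y = "cells")
}
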