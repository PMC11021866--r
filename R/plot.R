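# Figure analogues: delta-index genome scan and trait histograms.

#' Plot a delta-index sliding-window scan
#'
#' Draws the window mean delta-index along each chromosome with the
#' simulated 95% (and, when present, 99%) null envelopes, highlighting
#' significant windows; candidate intervals can be shaded.
#'
#' @param scan a `window_scan` from [sliding_window_scan()].
#' @param intervals optional `candidate_intervals` to shade.
#' @return a ggplot object.
#' @export
plot_delta_scan <- function(scan, intervals = NULL) {
  df <- scan[!is.na(scan$mean_delta), , drop = FALSE]
  df$mid_mb <- (df$start + df$end) / 2 / 1e6
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$mean_delta))
  if (!all(is.na(df$ci95_lo))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci95_lo, ymax = .data$ci95_hi),
      fill = "steelblue", alpha = 0.25)
  }
  if (!all(is.na(df$ci99_lo))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci99_lo, ymax = .data$ci99_hi),
      fill = "steelblue", alpha = 0.12)
  }
  if (!is.null(intervals) && nrow(intervals)) {
    iv <- intervals
    iv$xmin <- iv$start / 1e6; iv$xmax <- iv$end / 1e6
    p <- p + ggplot2::geom_rect(
      data = iv, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta ~ "index")) +
    ggplot2::theme_minimal()
}

#' Histogram of a fruit-size trait
#'
#' @param values numeric trait values.
#' @param bins number of bins.
#' @param xlab axis label.
#' @return a ggplot object.
#' @export
plot_trait_histogram <- function(values, bins = 20, xlab = "trait value") {
  df <- data.frame(x = values[!is.na(values)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = xlab, y = "count") +
    ggplot2::theme_minimal()
}
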