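#' Plot all pupil traces of one participant as semitransparent lines
#'
#' The classic data-quality view: good data is a tangle of lines;
#' unreconstructed blinks show as spikes shooting downwards out of it.
#' Collapse across conditions when judging quality.
#'
#' @param data A trial table.
#' @param col Pupil series column.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_traces <- function(data, col = "pupil", alpha = 0.2) {
  meta <- series_meta(data, col)
  m <- data[[col]]
  dt <- 1000 / meta$rate_hz
  d <- tibble::tibble(
    trial = rep(seq_len(nrow(m)), times = ncol(m)),
    time_ms = rep(meta$t0_ms + (seq_len(ncol(m)) - 1) * dt,
                  each = nrow(m)),
    pupil = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$pupil,
                                  group = .data$trial)) +
    ggplot2::geom_line(alpha = alpha, na.rm = TRUE) +
    ggplot2::labs(x = "Time (ms)", y = "Pupil size") +
    ggplot2::theme_minimal()
}

#' Histogram of baseline pupil sizes with exclusion bounds
#'
#' @param data A baseline-corrected trial table.
#' @param col Pupil series column (its `<col>_baseline` column is used).
#' @param z_thresh Exclusion threshold drawn as vertical lines.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_baseline_hist <- function(data, col = "pupil", z_thresh = 2,
                               bins = 30) {
  b <- data[[paste0(col, "_baseline")]]
  b <- b[!is.na(b)]
  mu <- mean(b)
  s <- stats::sd(b)
  ggplot2::ggplot(tibble::tibble(baseline = b),
                  ggplot2::aes(.data$baseline)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = mu + c(-1, 1) * z_thresh * s,
                        linetype = "dashed") +
    ggplot2::labs(x = "Baseline pupil size", y = "Trials") +
    ggplot2::theme_minimal()
}

#' Mean blinks per trial by condition and participant
#'
#' @param counts The `counts` tibble from [blink_counts()].
#' @return A ggplot object.
#' @export
plot_blink_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(factor(.data$condition),
                                       .data$mean_blinks,
                                       group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Condition", y = "Mean blinks per trial") +
    ggplot2::theme_minimal()
}

#' Gaze deviation from the display centre by condition
#'
#' @param gaze Output of [gaze_deviation()].
#' @return A ggplot object with horizontal and vertical panels.
#' @export
plot_gaze_deviation <- function(gaze) {
  d <- tidyr::pivot_longer(gaze, c("h_deg", "v_deg"),
                           names_to = "axis", values_to = "deg")
  d$axis <- ifelse(d$axis == "h_deg", "horizontal", "vertical")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$deg,
                                  colour = factor(.data$condition))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "Time (ms)", y = "Absolute deviation (deg)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Condition-wise mean traces with the cross-validation marker
#'
#' Trace plot of mean pupil size over time per condition; the vertical line
#' marks the mean of the samples at which each effect was tested.
#'
#' @param object A `pupil_cvtest`.
#' @param data The trial table the test was run on.
#' @param by Condition column for the separate lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pupil_cvtest <- function(object, data, by, ...) {
  meta <- series_meta(data, object$dv)
  m <- data[[object$dv]]
  dt <- 1000 / meta$rate_hz
  conds <- unique(data[[by]])
  d <- purrr::map_dfr(conds, function(cc) {
    i <- which(data[[by]] == cc)
    tibble::tibble(
      condition = cc,
      time_ms = meta$t0_ms + (seq_len(ncol(m)) - 1) * dt,
      pupil = nanmean_series(m[i, , drop = FALSE], "trials")
    )
  })
  marker <- meta$t0_ms + mean(object$chosen) * dt
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$pupil,
                                  colour = factor(.data$condition))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = marker, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = "Pupil size", colour = "Condition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
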