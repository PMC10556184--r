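#' Flag trials with unreconstructed downward spikes
#'
#' Operationalizes the visual check of plotting all baseline-corrected
#' traces as semitransparent lines and looking for spikes that shoot
#' downwards out of the tangle: a trial is a spike trial if any of its
#' samples lies more than `k` cross-trial spreads below the cross-trial
#' mean trace at that sample, or if any single-step change exceeds
#' `vel_bound` (units/ms). The spread is measured robustly (MAD, scaled to
#' the normal SD) so that the spikes themselves cannot inflate the
#' criterion and mask one another. As a rule of thumb no more than 5% of
#' trials should be flagged; more suggests revisiting the
#' blink-reconstruction parameters.
#'
#' @param values Baseline-corrected trials x samples matrix.
#' @param k Deviation threshold in cross-trial SDs (default 5).
#' @param vel_bound Single-step velocity bound in units/ms; the default
#'   `Inf` disables the velocity criterion, which does not transfer across
#'   arbitrary-unit scales without tuning.
#' @param rate_hz Sampling rate (needed only when `vel_bound` is finite).
#' @return List: `spike` (per-trial logical), `fraction`.
#' @export
spike_trials <- function(values, k = 5, vel_bound = Inf, rate_hz = NULL) {
  stopifnot(is.matrix(values))
  if (nrow(values) < 3) {
    stop("need at least 3 trials for a stable cross-trial mean trace",
         call. = FALSE)
  }
  mu <- colMeans(values, na.rm = TRUE)
  sd_s <- apply(values, 2, stats::mad, na.rm = TRUE)
  dev <- sweep(values, 2, mu)
  # deviation below the mean trace by more than k cross-trial SDs
  low <- dev < -k * matrix(pmax(sd_s, .Machine$double.eps),
                           nrow(values), ncol(values), byrow = TRUE)
  spike <- apply(low, 1, any, na.rm = TRUE)
  if (is.finite(vel_bound)) {
    if (is.null(rate_hz)) stop("rate_hz needed for the velocity bound",
                               call. = FALSE)
    dt <- 1000 / rate_hz
    step <- abs(t(diff(t(values)))) / dt
    fast <- apply(step > vel_bound, 1, any, na.rm = TRUE)
    spike <- spike | fast
  }
  list(spike = unname(spike), fraction = mean(spike))
}

#' Mean blink counts per trial by participant and condition
#'
#' Blinks are counted from recorded blink events when supplied; otherwise
#' maximal runs of missing samples of at least `min_dur_ms` in a
#' pre-reconstruction series column serve as an easy proxy. Blink rate
#' varies widely between participants, which is unproblematic; a systematic
#' difference between conditions is what the imbalance flag screens for
#' (max pairwise condition difference exceeding 25% of the grand mean -
#' an advisory heuristic, not an inferential test).
#'
#' @param data A trial table with the raw (pre-reconstruction) series.
#' @param by Name of the condition column.
#' @param col Series column used for the missing-run proxy.
#' @param events Optional tibble of blink events with a `row` column (one
#'   row per blink), e.g. the simulator's ground-truth blink log.
#' @param min_dur_ms Minimum missing-run duration counted as a blink.
#' @return List: `counts` (participant x condition tibble of mean blinks
#'   per trial), `imbalance` (logical flag), `per_trial` (vector).
#' @export
blink_counts <- function(data, by, col = "pupil", events = NULL,
                         min_dur_ms = 50) {
  n <- nrow(data)
  if (!is.null(events)) {
    per_trial <- tabulate(events$row, nbins = n)
  } else {
    meta <- series_meta(data, col)
    min_n <- max(1L, as.integer(round(min_dur_ms * meta$rate_hz / 1000)))
    m <- data[[col]]
    per_trial <- vapply(seq_len(n), function(i) {
      r <- rle(is.na(m[i, ]))
      sum(r$values & r$lengths >= min_n)
    }, integer(1))
  }
  d <- tibble::tibble(participant = as.character(data$participant),
                      condition = data[[by]], blinks = per_trial)
  counts <- d |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(mean_blinks = mean(.data$blinks), .groups = "drop")
  by_cond <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_blinks = mean(.data$blinks), .groups = "drop")
  grand <- mean(d$blinks)
  spread <- if (nrow(by_cond) > 1) diff(range(by_cond$mean_blinks)) else 0
  imbalance <- grand > 0 && spread > 0.25 * grand
  list(counts = counts, by_condition = by_cond,
       imbalance = imbalance, per_trial = per_trial)
}

#' Condition-wise gaze deviation from the display centre
#'
#' Converts the absolute horizontal and vertical deviation of gaze from the
#' display centre to degrees of visual angle and averages over trials,
#' per condition and time sample. Systematic condition differences in gaze
#' position can confound pupil-size comparisons and should be reported.
#'
#' @param data A trial table with `gaze_x` and `gaze_y` series columns.
#' @param by Name of the condition column.
#' @param center_px Display centre `c(x, y)` in pixels.
#' @param px_per_degree Pixels per degree of visual angle (> 0).
#' @param cols Names of the two gaze series columns.
#' @return A tibble: `condition`, `sample`, `time_ms`, `h_deg`, `v_deg`.
#' @export
gaze_deviation <- function(data, by, center_px, px_per_degree,
                           cols = c("gaze_x", "gaze_y")) {
  stopifnot(px_per_degree > 0, length(center_px) == 2)
  meta <- series_meta(data, cols[1])
  dx <- abs(data[[cols[1]]] - center_px[1]) / px_per_degree
  dy <- abs(data[[cols[2]]] - center_px[2]) / px_per_degree
  conds <- unique(data[[by]])
  dt <- 1000 / meta$rate_hz
  purrr::map_dfr(conds, function(cc) {
    i <- which(data[[by]] == cc)
    tibble::tibble(
      condition = cc,
      sample = seq_len(ncol(dx)) - 1L,
      time_ms = meta$t0_ms + (seq_len(ncol(dx)) - 1L) * dt,
      h_deg = nanmean_series(dx[i, , drop = FALSE], "trials"),
      v_deg = nanmean_series(dy[i, , drop = FALSE], "trials")
    )
  })
}

#' Aggregate data-quality report
#'
#' Combines the quantitative analogues of the four recommended visual
#' checks: the spike-trial fraction (with a flag above `spike_max`), the
#' missing-sample fraction, the baseline distribution summary, blink counts
#' per condition (with an imbalance flag), and gaze deviation by condition.
#' All metrics are computed per participant, collapsed across conditions
#' where the corresponding figures would be, so data quality is judged
#' without seeing whether the data show the hoped-for effect.
#'
#' @param data A baseline-corrected trial table (after [pp_baseline()]); the
#'   `<col>_baseline` scalar column must be present.
#' @param raw Optional pre-reconstruction trial table (same rows) for the
#'   blink-count proxy; defaults to `data`.
#' @param by Condition column name.
#' @param col Pupil series column.
#' @param center_px,px_per_degree Display geometry for gaze metrics; gaze
#'   metrics are skipped if the gaze columns are absent.
#' @param spike_k Spike criterion in SDs (default 5).
#' @param spike_max Flag threshold on the spike fraction (default 0.05).
#' @param blink_events Optional blink-event tibble (see [blink_counts()]).
#' @return A `pupil_qc` list: `per_participant` tibble (spike and missing
#'   fractions, baseline mean/SD/skew), `blinks`, `gaze`, `flags`.
#' @export
qc_report <- function(data, raw = data, by, col = "pupil",
                      center_px = NULL, px_per_degree = NULL,
                      spike_k = 5, spike_max = 0.05, blink_events = NULL) {
  bcol <- paste0(col, "_baseline")
  if (!bcol %in% names(data)) {
    stop("run pp_baseline() first: `", bcol, "` column is missing",
         call. = FALSE)
  }
  parts <- unique(as.character(data$participant))
  pp <- purrr::map_dfr(parts, function(p) {
    i <- which(as.character(data$participant) == p)
    m <- data[[col]][i, , drop = FALSE]
    sp <- spike_trials(m, k = spike_k)
    b <- data[[bcol]][i]
    bc <- b[!is.na(b)]
    skew <- if (length(bc) > 2 && stats::sd(bc) > 0) {
      mean((bc - mean(bc))^3) / stats::sd(bc)^3
    } else {
      NA_real_
    }
    tibble::tibble(
      participant = p,
      n_trials = length(i),
      spike_fraction = sp$fraction,
      missing_fraction = mean(is.na(m)),
      baseline_mean = mean(bc),
      baseline_sd = stats::sd(bc),
      baseline_skew = skew
    )
  })
  bl <- blink_counts(raw, by = by, col = col, events = blink_events)
  gz <- NULL
  if (!is.null(center_px) && !is.null(px_per_degree) &&
      all(c("gaze_x", "gaze_y") %in% series_cols(raw))) {
    gz <- gaze_deviation(raw, by = by, center_px = center_px,
                         px_per_degree = px_per_degree)
  }
  gaze_imbalance <- FALSE
  if (!is.null(gz)) {
    gm <- gz |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(h = mean(.data$h_deg, na.rm = TRUE),
                       v = mean(.data$v_deg, na.rm = TRUE), .groups = "drop")
    gaze_imbalance <- any(
      diff(range(gm$h)) > 0.25 * max(mean(gm$h), 1e-12),
      diff(range(gm$v)) > 0.25 * max(mean(gm$v), 1e-12)
    )
  }
  flags <- list(
    spikes = any(pp$spike_fraction > spike_max),
    blink_imbalance = isTRUE(bl$imbalance),
    gaze_imbalance = gaze_imbalance
  )
  structure(list(per_participant = pp, blinks = bl, gaze = gz,
                 flags = flags, spike_max = spike_max),
            class = "pupil_qc")
}

#' @export
print.pupil_qc <- function(x, ...) {
  cat("Data-quality report (", nrow(x$per_participant),
      " participant(s))\n", sep = "")
  print(x$per_participant)
  cat("Flags: spikes>", x$spike_max, ": ", x$flags$spikes,
      "; blink imbalance: ", x$flags$blink_imbalance,
      "; gaze imbalance: ", x$flags$gaze_imbalance, "\n", sep = "")
  invisible(x)
}
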