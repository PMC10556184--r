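#' Ground-truth description of a simulated pupillometry experiment
#'
#' Collects every tunable of the simulator in one validated list. The
#' defaults describe a small but realistic video-based recording: a 3000 ms
#' epoch at 1000 Hz, pupil size in arbitrary units centred near 1800 with a
#' between-participant SD of 100, slow arousal drift (sinusoid, 60 units
#' amplitude, 10 s period, random phase per trial; slow waves of roughly a
#' hundred units peak-to-peak are typical of arbitrary-unit recordings)
#' plus a trial-to-trial baseline shift (SD 50), a condition effect that follows a task-evoked
#' response kernel inside the effect window, white measurement noise of
#' 1 unit per sample, and Poisson-distributed blinks of 100-400 ms.
#'
#' @param n_participants Number of participants.
#' @param trials_per_participant Trials per participant (balanced across
#'   conditions; must be a multiple of `length(condition_values)`).
#' @param rate_hz Sampling rate (Hz).
#' @param epoch_ms Epoch duration (ms).
#' @param condition_values Numeric effect coding of the conditions
#'   (default near/medium/far as -1, 0, 1).
#' @param effect_size Peak pupil-size difference, in signal units, per unit
#'   of the condition coding.
#' @param effect_window `c(start_ms, end_ms)`: the effect is zero outside
#'   this half-open window.
#' @param kernel_shape,kernel_tpeak_ms Response-kernel parameters; the
#'   kernel peaks `kernel_tpeak_ms` after the start of the effect window.
#' @param drift_amplitude,drift_period_ms Slow sinusoidal drift (units, ms).
#' @param baseline_sd Trial-to-trial baseline shift SD (units).
#' @param intercept_mean,intercept_sd Participant random intercept (units).
#' @param slope_sd Participant random slope SD on the condition effect.
#' @param noise_sd White measurement noise SD per sample (units).
#' @param blink_rate Mean number of blinks per trial (Poisson).
#' @param blink_dur_ms Range of blink (fully-closed) durations, ms.
#' @param blink_ramp_ms Eyelid closing/opening ramp duration, ms.
#' @param long_blinks If `TRUE`, blink durations may exceed 500 ms to
#'   exercise the no-interpolation path.
#' @param gaze_noise_sd_deg Gaze noise SD in degrees.
#' @param px_per_degree Pixels per degree of visual angle.
#' @param center_px Display centre `c(x, y)` in pixels.
#' @param seed Integer seed; the simulator is bit-reproducible given the seed.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_participants = 10,
                           trials_per_participant = 39,
                           rate_hz = 1000,
                           epoch_ms = 3000,
                           condition_values = c(near = -1, medium = 0, far = 1),
                           effect_size = 50,
                           effect_window = c(750, 3000),
                           kernel_shape = 10.1,
                           kernel_tpeak_ms = 1000,
                           drift_amplitude = 60,
                           drift_period_ms = 10000,
                           baseline_sd = 50,
                           intercept_mean = 1800,
                           intercept_sd = 100,
                           slope_sd = 10,
                           noise_sd = 1,
                           blink_rate = 1,
                           blink_dur_ms = c(100, 400),
                           blink_ramp_ms = 10,
                           long_blinks = FALSE,
                           gaze_noise_sd_deg = 0.3,
                           px_per_degree = 35,
                           center_px = c(512, 384),
                           seed = 1) {
  spec <- as.list(environment())
  stopifnot(
    n_participants >= 1, trials_per_participant >= 1,
    rate_hz > 0, epoch_ms > 0,
    length(condition_values) >= 1,
    effect_window[1] < effect_window[2],
    effect_window[1] >= 0, effect_window[2] <= epoch_ms,
    kernel_shape > 0, kernel_tpeak_ms > 0,
    drift_amplitude >= 0, drift_period_ms > 0, baseline_sd >= 0,
    intercept_sd >= 0, slope_sd >= 0, noise_sd >= 0,
    blink_rate >= 0, blink_dur_ms[1] > 0, blink_dur_ms[1] <= blink_dur_ms[2],
    blink_ramp_ms > 0, gaze_noise_sd_deg >= 0, px_per_degree > 0
  )
  if (kernel_tpeak_ms >= epoch_ms) {
    stop("kernel time-to-peak must be shorter than the epoch", call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Task-evoked pupil response kernel
#'
#' A gamma/Erlang-shaped curve `h(t) = (t / tpeak)^s * exp(s * (1 - t / tpeak))`
#' for `t >= 0`: nonnegative, single-peaked, and normalized so its maximum is
#' exactly 1 at `tpeak_ms`. With the default shape the rise to peak takes
#' about one second, matching the sluggish dilation evoked by a discrete
#' stimulus.
#'
#' @param t_ms Numeric vector of times (ms) relative to kernel onset;
#'   negative times map to 0.
#' @param shape Shape parameter (> 0); larger is more sharply peaked.
#' @param tpeak_ms Time to peak (ms).
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @export
response_kernel <- function(t_ms, shape = 10.1, tpeak_ms = 1000) {
  stopifnot(shape > 0, tpeak_ms > 0)
  h <- ifelse(t_ms <= 0, 0,
              (t_ms / tpeak_ms)^shape * exp(shape * (1 - t_ms / tpeak_ms)))
  h
}

#' Simulate a trial-epoched pupillometry dataset with known ground truth
#'
#' Each trial's pupil trace is
#' `intercept_p + drift + baseline_shift + slope_p * code * kernel + noise`,
#' where the kernel is restricted to the effect window. Blinks are then
#' injected with the characteristic morphology: a sharp ramp down to zero
#' pupil size (eyelid closing), a fully-missing period (`NA`), and a sharp
#' ramp back up. The pre-injection trace is retained in the ground-truth
#' record so reconstruction error can be scored exactly. Gaze x/y series
#' jitter around the display centre.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `data` (a [trial_table()] with scalar columns
#'   `participant`, `trial`, `ecc` (condition label), `ecc_code` (numeric
#'   coding), and series columns `pupil`, `gaze_x`, `gaze_y`) and `truth`
#'   (list: `clean` pre-blink pupil matrix, `blinks` tibble of injected blink
#'   extents, `effect_window`, `spec`).
#' @examples
#' sim <- simulate_dataset(synthetic_spec(n_participants = 2,
#'   trials_per_participant = 6, rate_hz = 100, epoch_ms = 500,
#'   effect_window = c(260, 500)))
#' sim$data
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)

  n_s <- as.integer(round(spec$epoch_ms * spec$rate_hz / 1000))
  dt <- 1000 / spec$rate_hz
  t_ms <- (seq_len(n_s) - 1) * dt
  n_p <- spec$n_participants
  n_t <- spec$trials_per_participant
  n <- n_p * n_t

  codes <- spec$condition_values
  labels <- names(codes) %||% as.character(codes)
  if (is.null(names(codes))) names(codes) <- labels

  # kernel restricted to the effect window, time measured from window start
  kern <- response_kernel(t_ms - spec$effect_window[1],
                          spec$kernel_shape, spec$kernel_tpeak_ms)
  kern[t_ms < spec$effect_window[1] | t_ms >= spec$effect_window[2]] <- 0

  intercepts <- stats::rnorm(n_p, spec$intercept_mean, spec$intercept_sd)
  slopes <- stats::rnorm(n_p, spec$effect_size, spec$slope_sd)

  pupil <- matrix(NA_real_, n, n_s)
  gx <- matrix(NA_real_, n, n_s)
  gy <- matrix(NA_real_, n, n_s)
  participant <- character(n)
  trial <- integer(n)
  cond_lab <- character(n)
  cond_code <- numeric(n)
  blink_log <- list()

  ramp_n <- max(1L, as.integer(round(spec$blink_ramp_ms / dt)))
  row <- 0L
  for (p in seq_len(n_p)) {
    # balanced condition sequence, shuffled deterministically under the seed
    base_seq <- rep(seq_along(codes), length.out = n_t)
    cond_idx <- sample(base_seq)
    for (tr in seq_len(n_t)) {
      row <- row + 1L
      code <- unname(codes[cond_idx[tr]])
      phase <- stats::runif(1, 0, spec$drift_period_ms)
      drift <- spec$drift_amplitude *
        sin(2 * pi * (t_ms + phase) / spec$drift_period_ms)
      shift <- stats::rnorm(1, 0, spec$baseline_sd)
      trace <- intercepts[p] + drift + shift +
        slopes[p] * code * kern +
        stats::rnorm(n_s, 0, spec$noise_sd)
      pupil[row, ] <- trace
      gx[row, ] <- spec$center_px[1] +
        stats::rnorm(n_s, 0, spec$gaze_noise_sd_deg * spec$px_per_degree)
      gy[row, ] <- spec$center_px[2] +
        stats::rnorm(n_s, 0, spec$gaze_noise_sd_deg * spec$px_per_degree)
      participant[row] <- sprintf("p%02d", p)
      trial[row] <- tr
      cond_lab[row] <- labels[cond_idx[tr]]
      cond_code[row] <- code
    }
  }
  clean <- pupil

  # blink injection: ramp down to 0, missing, ramp back up
  max_dur <- if (spec$long_blinks) spec$blink_dur_ms[2] * 2 else
    spec$blink_dur_ms[2]
  for (row in seq_len(n)) {
    n_blinks <- stats::rpois(1, spec$blink_rate)
    if (n_blinks == 0) next
    for (b in seq_len(n_blinks)) {
      dur_ms <- stats::runif(1, spec$blink_dur_ms[1], max_dur)
      dur_n <- max(1L, as.integer(round(dur_ms / dt)))
      lo <- 2L * ramp_n + 2L
      hi <- n_s - dur_n - 2L * ramp_n - 1L
      if (hi <= lo) next
      onset <- as.integer(floor(stats::runif(1, lo, hi)))
      down <- onset:(onset + ramp_n - 1L)
      gap <- (onset + ramp_n):(onset + ramp_n + dur_n - 1L)
      up <- (onset + ramp_n + dur_n):(onset + 2L * ramp_n + dur_n - 1L)
      # ramps approach but never reach 0: a recorded 0 is the missing code
      ramp <- seq(1, 0, length.out = ramp_n + 1L)[seq_len(ramp_n)]
      pupil[row, down] <- clean[row, onset] * ramp
      pupil[row, gap] <- NA_real_
      pupil[row, up] <- clean[row, up[length(up)] + 1L] * rev(ramp)
      blink_log[[length(blink_log) + 1L]] <- tibble::tibble(
        row = row, onset_sample = onset - 1L,
        end_sample = onset + 2L * ramp_n + dur_n - 2L,
        dur_ms = dur_ms)
    }
  }

  # no gaze is recorded while the eyelid is fully closed
  gx[is.na(pupil)] <- NA_real_
  gy[is.na(pupil)] <- NA_real_

  scalars <- tibble::tibble(
    participant = participant, trial = trial,
    ecc = cond_lab, ecc_code = cond_code
  )
  data <- trial_table(scalars,
                      series = list(pupil = pupil, gaze_x = gx, gaze_y = gy),
                      rate_hz = spec$rate_hz, t0_ms = 0)
  truth <- list(
    clean = clean,
    blinks = if (length(blink_log)) dplyr::bind_rows(blink_log) else
      tibble::tibble(row = integer(), onset_sample = integer(),
                     end_sample = integer(), dur_ms = numeric()),
    effect_window = spec$effect_window,
    kernel = kern,
    intercepts = intercepts,
    slopes = slopes,
    spec = spec
  )
  list(data = data, truth = truth)
}

#' Inject unreconstructed downward spikes into a series column
#'
#' Fixture generator for the data-quality checks: a chosen fraction of trials
#' receives one brief downward spike far outside the normal trace envelope.
#'
#' @param data A trial table.
#' @param fraction Fraction of trials to affect, in `[0, 1]`;
#'   exactly `round(fraction * n_trials)` trials are hit.
#' @param magnitude Spike depth in signal units (subtracted).
#' @param col Series column to modify (default `"pupil"`).
#' @param width_ms Spike width (ms).
#' @param seed Seed controlling which trials and samples are hit.
#' @return A list: `data` (modified table) and `rows` (affected row indices).
#' @export
inject_spikes <- function(data, fraction, magnitude = 500, col = "pupil",
                          width_ms = 30, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(data)
  k <- round(fraction * n)
  if (k == 0) return(list(data = data, rows = integer()))
  withr::local_seed(seed)
  rows <- sort(sample.int(n, k))
  m <- data[[col]]
  meta <- series_meta(data, col)
  w <- max(3L, as.integer(round(width_ms * meta$rate_hz / 1000)))
  half <- w %/% 2L
  dip <- magnitude * (1 - abs(seq(-1, 1, length.out = w)))
  for (r in rows) {
    centre <- sample.int(ncol(m) - w - 2L, 1) + half + 1L
    idx <- (centre - half):(centre - half + w - 1L)
    m[r, idx] <- m[r, idx] - dip
  }
  data[[col]] <- m
  list(data = data, rows = rows)
}
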