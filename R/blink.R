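#' Tunables of the blink-reconstruction algorithm
#'
#' Velocity thresholds are expressed in signal units per ms and are scaled by
#' the trace's amplitude (`SD / 100`, floored at an SD of 1 unit) so the same
#' defaults behave sensibly across arbitrary-unit scales. An eyelid closing
#' over a trace of typical amplitude produces velocities one to two orders of
#' magnitude above these thresholds, while smoothed physiological
#' pupil-size change stays well below them.
#'
#' @param vt_start Onset threshold: a blink starts when the (smoothed)
#'   velocity falls below `-vt_start * SD / 100` units/ms.
#' @param vt_end Offset threshold: after the reopening rise, the blink ends
#'   when velocity falls back below `vt_end * SD / 100` units/ms.
#' @param maxdur_ms Maximum reconstructable blink duration (default 500 ms);
#'   longer blink-like periods are marked missing, never interpolated.
#' @param blink_margin_ms Margin around each blink treated as unreliable
#'   (default 10 ms).
#' @param smooth_winlen_ms Moving-average window used before velocity
#'   estimation (default 10 ms).
#' @param std_thresh Outlier cut: samples deviating more than this many SDs
#'   from the trace mean are marked missing (default 3).
#' @param gap_margin_ms Margin marked missing around every remaining missing
#'   period (default 20 ms).
#' @return A validated `blink_params` list.
#' @export
blink_params <- function(vt_start = 5, vt_end = 5, maxdur_ms = 500,
                         blink_margin_ms = 10, smooth_winlen_ms = 10,
                         std_thresh = 3, gap_margin_ms = 20) {
  p <- as.list(environment())
  stopifnot(vt_start > 0, vt_end > 0, maxdur_ms > 0, blink_margin_ms > 0,
            smooth_winlen_ms > 0, std_thresh > 0, gap_margin_ms > 0,
            maxdur_ms > 2 * blink_margin_ms)
  class(p) <- "blink_params"
  p
}

# moving average ignoring NA; NA positions stay NA
smooth_na <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v))
  cc <- c(0, cumsum(cnt))
  half <- k %/% 2
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (k - 1 - half))
  s <- (cs[hi + 1] - cs[lo]) / pmax(1, cc[hi + 1] - cc[lo])
  s[is.na(x)] <- NA_real_
  s
}

# widen NA runs by m samples on both sides; if `touched` is given, only
# runs intersecting it are widened (keeps the procedure idempotent: margins
# are applied once, around missingness derived during the current call)
widen_na <- function(x, m, touched = NULL) {
  if (m <= 0 || !anyNA(x)) return(x)
  na <- is.na(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    if (!is.null(touched) && !any(touched[starts[i]:ends[i]])) next
    lo <- max(1, starts[i] - m)
    hi <- min(length(x), ends[i] + m)
    x[lo:hi] <- NA_real_
  }
  x
}

#' Reconstruct blinks in a single pupil trace
#'
#' Recursive velocity-based blink reconstruction. Each pass smooths a working
#' copy of the trace, estimates velocity, and locates the earliest blink: a
#' negative velocity excursion past the onset threshold (eyelid closing),
#' followed - possibly across a run of missing samples - by a rapid rise
#' (eyelid reopening) that then stabilizes below the offset threshold. The
#' blink extent, widened by `blink_margin_ms` on both sides, is interpolated
#' with a cubic spline through four anchor points (two before onset, two
#' after offset, spaced one extent-length apart); if an anchor falls outside
#' the trace or on missing data, a straight line between the onset and offset
#' anchors is used instead. Extents longer than `maxdur_ms` are marked
#' missing and never interpolated. When no further blink is found, samples
#' deviating more than `std_thresh` SD from the trace mean or moving faster
#' than the onset threshold are marked missing, and finally every missing run
#' is widened by `gap_margin_ms`.
#'
#' Valid samples outside blink neighbourhoods are returned bit-identical;
#' the smoothing only ever affects detection, not output values.
#'
#' @param values Numeric vector: one epoch's pupil samples; missing is `NA`
#'   (raw 0-coded missing must already be recoded).
#' @param rate_hz Sampling rate in Hz.
#' @param params A [blink_params()].
#' @return A list: `values` (reconstructed trace), `report` (tibble with
#'   `n_blinks`, `n_cubic`, `n_linear`, `n_marked_missing`, `all_missing`).
#' @export
reconstruct_blinks <- function(values, rate_hz, params = blink_params()) {
  stopifnot(inherits(params, "blink_params"), rate_hz > 0)
  n <- length(values)
  dt <- 1000 / rate_hz
  k <- max(1L, as.integer(round(params$smooth_winlen_ms / dt)))
  if (n < k) {
    stop("trace (", n, " samples) is shorter than the smoothing window",
         call. = FALSE)
  }
  report <- tibble::tibble(n_blinks = 0L, n_cubic = 0L, n_linear = 0L,
                           n_marked_missing = 0L, all_missing = FALSE)
  if (all(is.na(values))) {
    warning("all-missing trace returned unchanged", call. = FALSE)
    report$all_missing <- TRUE
    return(list(values = values, report = report))
  }

  # The full pass (threshold calibration -> recursive blink detection and
  # interpolation -> outlier sweep -> gap margins) is iterated until the
  # trace no longer changes. The returned trace is therefore a fixed point
  # of the pass, which makes the whole function idempotent: re-applying it
  # starts the same iteration at the fixed point and stops immediately.
  x <- as.numeric(values)
  for (round_i in seq_len(10L)) {
    res <- blink_pass(x, n, dt, k, params)
    report$n_blinks <- report$n_blinks + res$n_blinks
    report$n_cubic <- report$n_cubic + res$n_cubic
    report$n_linear <- report$n_linear + res$n_linear
    if (identical(res$x, x)) break
    x <- res$x
  }
  report$n_marked_missing <- sum(is.na(x) & !is.na(values))
  list(values = x, report = report)
}

# one full pass of the reconstruction procedure over a trace
blink_pass <- function(x, n, dt, k, params) {
  n_blinks <- n_cubic <- n_linear <- 0L
  margin_n <- max(1L, as.integer(round(params$blink_margin_ms / dt)))
  handled <- rep(FALSE, n)
  touched <- rep(FALSE, n)

  # Velocity thresholds are calibrated to the recording noise:
  # eyelid-driven velocities exceed measurement noise and physiological
  # pupil-size change by orders of magnitude, so the thresholds sit at
  # 6 robust SDs of the smoothed-velocity noise for the default
  # vt_start/vt_end of 5 (a moving average of width k attenuates white
  # noise of SD sigma to a velocity SD of about sigma * sqrt(2) / (k * dt)).
  # The noise SD is the MAD of successive differences, maximized over 10
  # contiguous segments so that smooth (e.g. interpolated) stretches cannot
  # drag it down.
  dx <- diff(x)
  segs <- split(dx, cut(seq_along(dx), breaks = min(10, length(dx)),
                        labels = FALSE))
  seg_mads <- vapply(segs, function(sg) {
    if (sum(!is.na(sg)) < 10) NA_real_ else stats::mad(sg, na.rm = TRUE)
  }, numeric(1))
  noise <- if (all(is.na(seg_mads))) 0 else max(seg_mads, na.rm = TRUE)
  scale <- max(1 / 100, (6 / 5) * noise / (k * dt))
  vt_on <- -params$vt_start * scale
  vt_off <- params$vt_end * scale

  for (pass in seq_len(100L)) {
    s <- smooth_na(x, k)
    v <- c(diff(s) / dt, NA_real_)

    cand <- which(!is.na(v) & v < vt_on & !handled)
    if (length(cand) == 0) break
    onset <- cand[1]

    # walk forward: reopening = velocity above +vt_off; then stabilization =
    # velocity back below +vt_off. NA velocities are treated as inside the
    # blink. A blink running off the end of the trace is marked missing.
    j <- onset + 1L
    reopen <- NA_integer_
    while (j < n) {
      if (!is.na(v[j]) && v[j] > vt_off) { reopen <- j; break }
      j <- j + 1L
    }
    if (is.na(reopen)) {
      # no reopening anywhere ahead: a blink truncated by the end of the
      # trace only when missing data confirms the eye stayed shut;
      # otherwise this is a slow decline, not a blink
      if (anyNA(x[onset:n])) {
        lo <- max(1L, onset - margin_n)
        x[lo:n] <- NA_real_
        handled[lo:n] <- TRUE
        touched[lo:n] <- TRUE
        n_blinks <- n_blinks + 1L
      } else {
        handled[onset:n] <- TRUE
      }
      next
    }
    kk <- reopen + 1L
    end <- NA_integer_
    while (kk < n) {
      if (!is.na(v[kk]) && v[kk] < vt_off) { end <- kk; break }
      kk <- kk + 1L
    }
    if (is.na(end)) {
      lo <- max(1L, onset - margin_n)
      x[lo:n] <- NA_real_
      handled[lo:n] <- TRUE
      touched[lo:n] <- TRUE
      n_blinks <- n_blinks + 1L
      next
    }

    ext_lo <- max(1L, onset - margin_n)
    ext_hi <- min(n, end + margin_n)
    handled[ext_lo:ext_hi] <- TRUE
    touched[ext_lo:ext_hi] <- TRUE
    n_blinks <- n_blinks + 1L
    ext_len <- ext_hi - ext_lo

    if ((ext_hi - ext_lo + 1L) * dt > params$maxdur_ms) {
      x[ext_lo:ext_hi] <- NA_real_
      next
    }

    a <- c(ext_lo - ext_len, ext_lo, ext_hi, ext_hi + ext_len)
    anchors_ok <- all(a >= 1 & a <= n) && !anyNA(x[a[a >= 1 & a <= n]])
    if (anchors_ok && a[2] + 1L <= a[3] - 1L) {
      fill <- (a[2] + 1L):(a[3] - 1L)
      x[fill] <- stats::spline(a, x[a], xout = fill, method = "fmm")$y
      n_cubic <- n_cubic + length(fill)
    } else if (!is.na(x[ext_lo]) && !is.na(x[ext_hi]) &&
               ext_lo + 1L <= ext_hi - 1L) {
      fill <- (ext_lo + 1L):(ext_hi - 1L)
      x[fill] <- x[ext_lo] +
        (x[ext_hi] - x[ext_lo]) * (fill - ext_lo) / (ext_hi - ext_lo)
      n_linear <- n_linear + length(fill)
    } else {
      x[ext_lo:ext_hi] <- NA_real_
    }
  }

  # remaining invalid data: amplitude outliers (mean/SD of the
  # post-interpolation trace, re-estimated after each removal until no
  # sample is marked) and residual fast transients (same velocity
  # thresholds as detection)
  for (sweep in seq_len(50L)) {
    s <- smooth_na(x, k)
    v <- c(diff(s) / dt, NA_real_)
    mu <- mean(x, na.rm = TRUE)
    sd_post <- stats::sd(x, na.rm = TRUE)
    bad <- (!is.na(x) & !is.na(sd_post) & sd_post > 0 &
              abs(x - mu) > params$std_thresh * sd_post) |
      (!is.na(v) & abs(v) > params$vt_start * scale)
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) break
    x[bad] <- NA_real_
    touched[bad] <- TRUE
  }

  gap_n <- max(1L, as.integer(round(params$gap_margin_ms / dt)))
  x <- widen_na(x, gap_n, touched)
  list(x = x, n_blinks = n_blinks, n_cubic = n_cubic, n_linear = n_linear)
}

#' Reconstruct blinks in every trial of a trial table
#'
#' Applies [reconstruct_blinks()] row-wise to one or more series columns.
#' This is the first preprocessing stage and must run before downsampling
#' (the velocity-based detection needs the original sampling rate); the
#' table's stage marker enforces the order.
#'
#' @param data A trial table.
#' @param cols Series columns to reconstruct (default `"pupil"`).
#' @param params A [blink_params()].
#' @return The table with reconstructed series and a `blink_report`
#'   attribute: one tibble row per (trial, column).
#' @export
pp_reconstruct <- function(data, cols = "pupil", params = blink_params()) {
  data <- advance_stage(data, "reconstruct")
  reports <- list()
  for (col in cols) {
    meta <- series_meta(data, col)
    m <- data[[col]]
    rep_rows <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
      res <- withCallingHandlers(
        reconstruct_blinks(m[i, ], meta$rate_hz, params),
        warning = function(w) invokeRestart("muffleWarning"))
      m[i, ] <- res$values
      rep_rows[[i]] <- res$report
    }
    data[[col]] <- m
    rp <- dplyr::bind_rows(rep_rows)
    rp$row <- seq_len(nrow(m))
    rp$column <- col
    reports[[col]] <- rp
  }
  attr(data, "blink_report") <- dplyr::bind_rows(reports)
  data
}
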