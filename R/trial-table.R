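#' Build a trial-epoched pupillometry table
#'
#' A trial table is a [tibble::tibble()] with one row per trial. Ordinary
#' (scalar) columns hold per-trial values such as the participant id,
#' condition codes, or response times. *Series* columns are numeric matrices
#' (trials x samples) holding one epoch of a continuously sampled signal per
#' trial; all epochs in one series column share a sampling rate and an
#' epoch-zero time, stored in the table's `series_meta` attribute. Missing or
#' invalid samples are `NA`; raw streams that code missing pupil size as 0
#' must be recoded on ingest (the parsers do this).
#'
#' Row order is meaningful: trials are chronological within participant and
#' participants are concatenated, because the interleaved cross-validation
#' split operates on row order.
#'
#' @param scalars A data frame (or list coercible to one) of per-trial scalar
#'   variables. Must contain a `participant` column.
#' @param series Named list of numeric matrices, each with `nrow(scalars)`
#'   rows. Ragged epochs must already be right-padded with `NA`.
#' @param rate_hz Sampling rate in Hz shared by all series columns, or a named
#'   list/vector giving one rate per series column.
#' @param t0_ms Time of sample 0 relative to epoch onset, in ms (default 0),
#'   scalar or named per series column.
#'
#' @return A `trial_tbl`: a tibble with matrix series columns and a
#'   `series_meta` attribute mapping each series column to its
#'   `rate_hz` and `t0_ms`.
#' @examples
#' tt <- trial_table(
#'   data.frame(participant = c("s1", "s1"), ecc = c(-1, 1)),
#'   series = list(pupil = matrix(rnorm(20), nrow = 2)),
#'   rate_hz = 100
#' )
#' series_meta(tt, "pupil")
#' @export
trial_table <- function(scalars, series = list(), rate_hz = NULL, t0_ms = 0) {
  scalars <- tibble::as_tibble(scalars)
  if (!"participant" %in% names(scalars)) {
    stop("trial_table requires a `participant` scalar column", call. = FALSE)
  }
  if (length(series) > 0 && is.null(rate_hz)) {
    stop("`rate_hz` must be supplied when series columns are given",
         call. = FALSE)
  }
  nm <- names(series)
  if (length(series) > 0 && (is.null(nm) || any(nm == ""))) {
    stop("all series columns must be named", call. = FALSE)
  }
  meta <- list()
  out <- scalars
  for (s in nm) {
    m <- series[[s]]
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(scalars))
    storage.mode(m) <- "double"
    if (nrow(m) != nrow(scalars)) {
      stop("series column `", s, "` has ", nrow(m), " rows but the table has ",
           nrow(scalars), " trials", call. = FALSE)
    }
    r <- if (length(rate_hz) > 1 || !is.null(names(rate_hz))) {
      as.numeric(rate_hz[[s]])
    } else {
      as.numeric(rate_hz)
    }
    t0 <- if (length(t0_ms) > 1 || !is.null(names(t0_ms))) {
      as.numeric(t0_ms[[s]])
    } else {
      as.numeric(t0_ms)
    }
    if (!is.finite(r) || r <= 0) {
      stop("rate_hz for series `", s, "` must be > 0", call. = FALSE)
    }
    bad <- !is.na(m) & !is.finite(m)
    if (any(bad)) {
      stop("series column `", s, "` contains non-finite, non-NA values",
           call. = FALSE)
    }
    dimnames(m) <- NULL
    out[[s]] <- m
    meta[[s]] <- list(rate_hz = r, t0_ms = t0)
  }
  attr(out, "series_meta") <- meta
  class(out) <- c("trial_tbl", class(out))
  out
}

#' @export
print.trial_tbl <- function(x, ...) {
  sm <- attr(x, "series_meta")
  cat("# A trial table: ", nrow(x), " trials, ",
      length(unique(x$participant)), " participant(s)\n", sep = "")
  for (s in names(sm)) {
    cat("# series `", s, "`: ", ncol(x[[s]]), " samples @ ",
        sm[[s]]$rate_hz, " Hz, t0 = ", sm[[s]]$t0_ms, " ms\n", sep = "")
  }
  NextMethod()
}

#' Names of the series (matrix) columns of a trial table
#' @param data A trial table.
#' @return Character vector of series column names.
#' @export
series_cols <- function(data) {
  names(attr(data, "series_meta") %||% list())
}

#' Sampling metadata of one series column
#' @param data A trial table.
#' @param col Series column name.
#' @return A list with elements `rate_hz` and `t0_ms`.
#' @export
series_meta <- function(data, col) {
  sm <- attr(data, "series_meta")
  if (is.null(sm[[col]])) {
    stop("`", col, "` is not a series column; series columns are: ",
         paste(names(sm), collapse = ", "), call. = FALSE)
  }
  sm[[col]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define an epoch-relative time window
#'
#' Windows are half-open `[start_ms, end_ms)` in epoch-relative milliseconds;
#' sample `i` of a trace (0-based) covers
#' `[t0_ms + i * 1000 / rate_hz, t0_ms + (i + 1) * 1000 / rate_hz)`.
#'
#' @param start_ms,end_ms Window bounds in ms, `start_ms < end_ms`.
#' @return A `time_window` object.
#' @export
time_window <- function(start_ms, end_ms) {
  stopifnot(is.numeric(start_ms), is.numeric(end_ms))
  if (!(start_ms < end_ms)) {
    stop("time_window requires start_ms < end_ms", call. = FALSE)
  }
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "time_window")
}

as_time_window <- function(x) {
  if (inherits(x, "time_window")) return(x)
  if (is.numeric(x) && length(x) == 2) return(time_window(x[1], x[2]))
  stop("cannot interpret window; supply time_window() or c(start, end)",
       call. = FALSE)
}

#' Map a time window to a sample-index range
#'
#' Returns the half-open 0-based index range of the samples whose coverage
#' intervals overlap the window. The range is never empty; a window with no
#' overlap with the epoch is an error naming the epoch extent.
#'
#' @param rate_hz Sampling rate in Hz.
#' @param t0_ms Time of sample 0 relative to epoch onset (ms).
#' @param n_samples Number of samples in the epoch.
#' @param window A [time_window()] or length-2 numeric `c(start_ms, end_ms)`.
#' @return Integer vector `c(first, end)`: 0-based half-open `[first, end)`.
#' @examples
#' window_to_samples(1000, 0, 3000, c(0, 50))   # samples [0, 50)
#' window_to_samples(100, 0, 300, c(750, 3000)) # samples [75, 300)
#' @export
window_to_samples <- function(rate_hz, t0_ms, n_samples, window) {
  w <- as_time_window(window)
  dt <- 1000 / rate_hz
  # sample i overlaps [s, e) iff t0 + i*dt < e and t0 + (i+1)*dt > s
  i_min <- max(0L, as.integer(floor((w$start_ms - t0_ms) / dt + 1e-9)))
  i_end <- min(as.integer(n_samples),
               as.integer(ceiling((w$end_ms - t0_ms) / dt - 1e-9)))
  if (i_min >= i_end) {
    extent <- c(t0_ms, t0_ms + n_samples * dt)
    stop(sprintf(
      "window [%g, %g) ms does not overlap the epoch extent [%g, %g) ms",
      w$start_ms, w$end_ms, extent[1], extent[2]), call. = FALSE)
  }
  c(i_min, i_end)
}

# 1-based R column indices for a window on a given series column
window_cols <- function(data, col, window) {
  m <- series_meta(data, col)
  rng <- window_to_samples(m$rate_hz, m$t0_ms, ncol(data[[col]]), window)
  seq.int(rng[1] + 1L, rng[2])
}

#' Mean of a series column ignoring missing values
#'
#' @param x A numeric matrix (trials x samples).
#' @param axis `"trials"` averages across trials (one value per sample);
#'   `"time"` averages across samples (one value per trial).
#' @return Numeric vector of means; an all-missing slice yields `NA`.
#' @export
nanmean_series <- function(x, axis = c("trials", "time")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(x), length(x) > 0)
  out <- if (axis == "trials") colMeans(x, na.rm = TRUE)
         else rowMeans(x, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  unname(out)
}

#' Write a trial table to a plain-text directory bundle
#'
#' The bundle holds `scalars.tsv` (tab-separated scalar columns),
#' `series_<name>.csv` (one comma-separated trials x samples matrix per
#' series column, missing cells empty), and `meta.json` (per-series
#' `rate_hz`, `t0_ms`, and any preprocessing stage marker).
#'
#' @param data A trial table.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- series_cols(data)
  scalars <- data[setdiff(names(data), sc)]
  readr::write_tsv(tibble::as_tibble(as.data.frame(scalars)),
                   file.path(dir, "scalars.tsv"), progress = FALSE)
  for (s in sc) {
    utils::write.table(data[[s]], file.path(dir, paste0("series_", s, ".csv")),
                       sep = ",", na = "", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(
    series = attr(data, "series_meta"),
    stage = attr(data, "pp_stage") %||% "raw"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial table from a directory bundle
#'
#' @param dir Directory written by [write_bundle()].
#' @return A trial table.
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  scalars <- readr::read_tsv(file.path(dir, "scalars.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  series <- list()
  rates <- list()
  t0s <- list()
  for (s in names(meta$series)) {
    m <- as.matrix(utils::read.table(
      file.path(dir, paste0("series_", s, ".csv")),
      sep = ",", na.strings = c("", "NA"), header = FALSE))
    dimnames(m) <- NULL
    series[[s]] <- m
    rates[[s]] <- meta$series[[s]]$rate_hz
    t0s[[s]] <- meta$series[[s]]$t0_ms
  }
  out <- trial_table(scalars, series, rate_hz = rates, t0_ms = t0s)
  if (!identical(meta$stage, "raw")) attr(out, "pp_stage") <- meta$stage
  out
}
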