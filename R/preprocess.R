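#' @keywords internal
#' Preprocessing stage tracking: the chain is reconstruct -> downsample ->
#' convert -> baseline -> exclude. Stages may be skipped but never reordered;
#' the blink detector needs the original sampling rate, calibration must see
#' uncorrected units, and exclusion needs baselines.
pp_stages <- c("raw", "reconstruct", "downsample", "convert",
               "baseline", "exclude")

advance_stage <- function(data, stage) {
  cur <- attr(data, "pp_stage") %||% "raw"
  if (match(stage, pp_stages) <= match(cur, pp_stages)) {
    stop("preprocessing out of order: `", stage, "` cannot follow `", cur,
         "`; the chain is ", paste(pp_stages[-1], collapse = " -> "),
         call. = FALSE)
  }
  attr(data, "pp_stage") <- stage
  data
}

#' Downsample a trace by an integer factor
#'
#' Each output sample is the mean of a block of `factor` consecutive input
#' samples, ignoring missing values; an all-missing block yields `NA`. A
#' trailing partial block is dropped. Block averaging is itself a box
#' low-pass filter, so no separate anti-alias filter is applied.
#'
#' @param values Numeric vector (one trace) or matrix (trials x samples).
#' @param factor Positive integer downsampling factor.
#' @return The same kind of object with `floor(n / factor)` samples.
#' @examples
#' downsample(c(1, 1, 3, 3), 2)  # c(1, 3)
#' @export
downsample <- function(values, factor) {
  if (!(is.numeric(factor) && length(factor) == 1 && factor >= 1 &&
        factor == round(factor))) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(values)
  if (is.matrix(values)) {
    n_out <- ncol(values) %/% factor
    stopifnot(n_out >= 1)
    out <- vapply(seq_len(n_out), function(b) {
      block <- values[, ((b - 1L) * factor + 1L):(b * factor), drop = FALSE]
      r <- rowMeans(block, na.rm = TRUE)
      r[is.nan(r)] <- NA_real_
      r
    }, numeric(nrow(values)))
    matrix(out, nrow = nrow(values))
  } else {
    n_out <- length(values) %/% factor
    stopifnot(n_out >= 1)
    out <- vapply(seq_len(n_out), function(b) {
      blk <- values[((b - 1L) * factor + 1L):(b * factor)]
      m <- mean(blk, na.rm = TRUE)
      if (is.nan(m)) NA_real_ else m
    }, numeric(1))
    out
  }
}

#' Downsample every series column of a trial table
#'
#' @param data A trial table.
#' @param factor Positive integer factor; sampling rates are divided by it.
#' @return The table with shortened series columns and updated metadata.
#' @export
pp_downsample <- function(data, factor) {
  data <- advance_stage(data, "downsample")
  sm <- attr(data, "series_meta")
  for (s in names(sm)) {
    data[[s]] <- downsample(data[[s]], factor)
    sm[[s]]$rate_hz <- sm[[s]]$rate_hz / factor
  }
  attr(data, "series_meta") <- sm
  data
}

#' Fit a pupil-size calibration curve
#'
#' Fits a conversion from recorded arbitrary units to millimetres of
#' diameter using ground-truth pairs, typically obtained by recording
#' printed circles of known size. The default functional form is a
#' two-parameter power law `mm = a * units^b` (fit by least squares on the
#' log scale, which linearizes the model); `form = "linear"` fits
#' `mm = a + b * units`. The recorded-unit/true-size relation of
#' video-based trackers is monotone but generally not linear.
#'
#' @param pairs Data frame with columns `mm` (true diameter) and `units`
#'   (recorded arbitrary units, strictly positive); at least 3 rows.
#' @param form `"power"` (default) or `"linear"`.
#' @return A `calibration_model` with fields `form`, `coef`, and `residuals`
#'   summary; `predict()` maps units to mm and is monotone on the data range.
#' @export
fit_calibration <- function(pairs, form = c("power", "linear")) {
  form <- match.arg(form)
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mm", "units") %in% names(pairs))) {
    stop("`pairs` needs columns `mm` and `units`", call. = FALSE)
  }
  pairs <- pairs[stats::complete.cases(pairs[c("mm", "units")]), ]
  if (nrow(pairs) < 3) {
    stop("calibration needs at least 3 (mm, units) pairs", call. = FALSE)
  }
  if (any(pairs$units <= 0)) {
    stop("recorded units must be strictly positive", call. = FALSE)
  }
  if (stats::sd(pairs$units) == 0 || stats::sd(pairs$mm) == 0) {
    stop("degenerate calibration pairs: zero variance", call. = FALSE)
  }
  if (form == "power") {
    fit <- stats::lm(log(mm) ~ log(units), data = pairs)
    co <- stats::coef(fit)
    coefs <- c(a = unname(exp(co[1])), b = unname(co[2]))
    pred <- coefs["a"] * pairs$units^coefs["b"]
  } else {
    fit <- stats::lm(mm ~ units, data = pairs)
    co <- stats::coef(fit)
    coefs <- c(a = unname(co[1]), b = unname(co[2]))
    pred <- coefs["a"] + coefs["b"] * pairs$units
  }
  res <- pairs$mm - pred
  grid <- seq(min(pairs$units), max(pairs$units), length.out = 101)
  gp <- if (form == "power") coefs["a"] * grid^coefs["b"] else
    coefs["a"] + coefs["b"] * grid
  if (any(diff(gp) <= 0)) {
    warning("fitted calibration is not monotonically increasing over the ",
            "observed range", call. = FALSE)
  }
  structure(list(form = form, coef = coefs,
                 range = range(pairs$units),
                 residuals = c(rmse = sqrt(mean(res^2)),
                               max_abs = max(abs(res)))),
            class = "calibration_model")
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  u <- if (is.list(newdata)) newdata$units else newdata
  if (object$form == "power") {
    out <- object$coef[["a"]] * u^object$coef[["b"]]
  } else {
    out <- object$coef[["a"]] + object$coef[["b"]] * u
  }
  out
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model (", x$form, "): ", sep = "")
  if (x$form == "power") {
    cat(sprintf("mm = %.6g * units^%.6g\n", x$coef[["a"]], x$coef[["b"]]))
  } else {
    cat(sprintf("mm = %.6g + %.6g * units\n", x$coef[["a"]], x$coef[["b"]]))
  }
  cat(sprintf("  fit on units in [%.4g, %.4g]; residual RMSE %.4g mm\n",
              x$range[1], x$range[2], x$residuals[["rmse"]]))
  invisible(x)
}

#' Convert a series column from arbitrary units to millimetres
#'
#' Elementwise transform through a fitted [fit_calibration()] model;
#' missing values pass through as missing. Inputs outside the model's
#' calibrated range are transformed anyway with a warning.
#'
#' @param data A trial table.
#' @param model A `calibration_model`.
#' @param cols Series columns to convert (default `"pupil"`).
#' @return The table with converted series (now in mm).
#' @export
pp_convert <- function(data, model, cols = "pupil") {
  stopifnot(inherits(model, "calibration_model"))
  data <- advance_stage(data, "convert")
  for (col in cols) {
    m <- data[[col]]
    ok <- !is.na(m)
    if (any(ok & (m < model$range[1] | m > model$range[2]))) {
      warning("values in `", col, "` fall outside the calibrated range [",
              model$range[1], ", ", model$range[2], "]; converted anyway",
              call. = FALSE)
    }
    m[ok] <- predict(model, m[ok])
    data[[col]] <- m
  }
  data
}

#' Baseline-correct a series matrix
#'
#' Per trial, the baseline `b` is the mean over the baseline window
#' (ignoring missing). Subtractive correction (recommended) returns
#' `values - b`; divisive returns `values / b`. A trial whose baseline
#' window is all-missing (or whose baseline is 0 under divisive mode)
#' yields an all-missing corrected trace and a missing baseline.
#'
#' @param values Trials x samples numeric matrix.
#' @param cols_idx 1-based column indices of the baseline window.
#' @param mode `"subtractive"` (default) or `"divisive"`.
#' @return List: `values` (corrected matrix), `baseline` (per-trial vector).
#' @export
baseline_correct <- function(values, cols_idx,
                             mode = c("subtractive", "divisive")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), length(cols_idx) >= 1)
  b <- rowMeans(values[, cols_idx, drop = FALSE], na.rm = TRUE)
  b[is.nan(b)] <- NA_real_
  if (mode == "divisive" && any(!is.na(b) & b == 0)) {
    warning("divisive baseline of 0 on ", sum(!is.na(b) & b == 0),
            " trial(s); their corrected traces are missing", call. = FALSE)
    b[!is.na(b) & b == 0] <- NA_real_
  }
  out <- if (mode == "subtractive") values - b else values / b
  out[is.na(b), ] <- NA_real_
  list(values = out, baseline = b)
}

#' Baseline-correct series columns of a trial table
#'
#' @param data A trial table.
#' @param window Baseline [time_window()] or `c(start_ms, end_ms)`, e.g. the
#'   first 50 ms of the epoch.
#' @param cols Series columns to correct (default `"pupil"`).
#' @param mode `"subtractive"` (default) or `"divisive"`.
#' @return The table with corrected series and, per corrected column, a new
#'   scalar column `<col>_baseline` holding the per-trial baseline for
#'   downstream exclusion.
#' @export
pp_baseline <- function(data, window, cols = "pupil",
                        mode = c("subtractive", "divisive")) {
  mode <- match.arg(mode)
  data <- advance_stage(data, "baseline")
  for (col in cols) {
    idx <- window_cols(data, col, window)
    res <- baseline_correct(data[[col]], idx, mode)
    data[[col]] <- res$values
    data[[paste0(col, "_baseline")]] <- res$baseline
  }
  data
}

#' Exclude trials with outlying baseline pupil size
#'
#' Baselines are z-scored separately within each participant (sample SD,
#' `n - 1` denominator) and trials with `|z| > z_thresh` or a missing
#' baseline are excluded. A participant with zero baseline variance gets
#' `z = 0` for all trials (none excluded) with a warning.
#'
#' @param data A data frame with a `participant` column (typically a trial
#'   table after [pp_baseline()]).
#' @param baseline Name of the baseline column (default `"pupil_baseline"`)
#'   or a numeric vector aligned with rows.
#' @param z_thresh Exclusion threshold in SD units (default 2).
#' @return List: `data` (filtered table), `keep` (logical mask over the
#'   input rows), `counts` (per-participant tibble of excluded trial
#'   counts), `z` (the z-scores).
#' @export
exclude_baseline_outliers <- function(data, baseline = "pupil_baseline",
                                      z_thresh = 2) {
  stopifnot(z_thresh > 0)
  b <- if (is.character(baseline)) data[[baseline]] else baseline
  if (is.null(b) || length(b) != nrow(data)) {
    stop("baseline values must align with table rows", call. = FALSE)
  }
  grp <- as.character(data$participant)
  z <- rep(NA_real_, length(b))
  zero_var <- character()
  for (p in unique(grp)) {
    i <- which(grp == p)
    bi <- b[i]
    if (sum(!is.na(bi)) < 2) {
      stop("participant ", p, " has fewer than 2 non-missing baselines",
           call. = FALSE)
    }
    s <- stats::sd(bi, na.rm = TRUE)
    if (s == 0) {
      zero_var <- c(zero_var, p)
      z[i] <- ifelse(is.na(bi), NA_real_, 0)
    } else {
      z[i] <- (bi - mean(bi, na.rm = TRUE)) / s
    }
  }
  if (length(zero_var)) {
    warning("zero baseline variance for participant(s) ",
            paste(zero_var, collapse = ", "), "; z set to 0", call. = FALSE)
  }
  keep <- !is.na(z) & abs(z) <= z_thresh
  out <- advance_stage(data, "exclude")[keep, ]
  counts <- tibble::tibble(participant = grp, excluded = !keep) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_excluded = sum(.data$excluded), .groups = "drop")
  list(data = out, keep = keep, counts = counts, z = z)
}
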