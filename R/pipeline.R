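#' Assemble and validate an end-to-end pipeline configuration
#'
#' Collects every stage's parameters in one validated object. Defaults match
#' the recommended workflow: blink reconstruction with a 500 ms maximum
#' blink, 10 ms blink margins and 20 ms gap margins, +/-3 SD outlier
#' removal; downsampling factor 10; subtractive baseline correction over the
#' first 50 ms; exclusion at |z| > 2; alpha .05; 4 folds; 1000 permutations.
#' Validation is exhaustive before any stage runs, so a bad configuration
#' never produces partial artifacts.
#'
#' @param input Path to an input bundle directory ([write_bundle()] layout)
#'   or an ASC log file, or a trial table.
#' @param output Output directory for artifacts.
#' @param pupil,condition Names of the pupil series column and the condition
#'   (fixed-effect) column.
#' @param blink A [blink_params()].
#' @param downsample_factor Integer >= 1 (1 disables downsampling).
#' @param calibration Optional path to a delimited file with columns
#'   `mm,units`, or a data frame; `NULL` skips unit conversion.
#' @param baseline_window Baseline window `c(start_ms, end_ms)`.
#' @param baseline_mode `"subtractive"` or `"divisive"`.
#' @param z_thresh Baseline-exclusion threshold (SD units).
#' @param method `"window"`, `"cluster"`, or `"crossval"`.
#' @param test_window Window for `method = "window"`.
#' @param alpha Significance level.
#' @param n_permutations Permutations for `method = "cluster"`.
#' @param n_folds Folds for `method = "crossval"`.
#' @param seed Seed for the permutation test.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, output,
                            pupil = "pupil", condition = "ecc_code",
                            blink = blink_params(),
                            downsample_factor = 10,
                            calibration = NULL,
                            baseline_window = c(0, 50),
                            baseline_mode = "subtractive",
                            z_thresh = 2,
                            method = "window",
                            test_window = c(750, 3000),
                            alpha = 0.05,
                            n_permutations = 1000,
                            n_folds = 4,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(inherits(blink, "blink_params"))
  if (!(is.numeric(downsample_factor) && downsample_factor >= 1 &&
        downsample_factor == round(downsample_factor))) {
    stop("downsample_factor must be a positive integer", call. = FALSE)
  }
  if (!baseline_mode %in% c("subtractive", "divisive")) {
    stop("baseline_mode must be 'subtractive' or 'divisive'", call. = FALSE)
  }
  if (!method %in% c("window", "cluster", "crossval")) {
    stop("method must be one of window/cluster/crossval", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, z_thresh > 0, n_permutations >= 100,
            n_folds >= 2, baseline_window[1] < baseline_window[2])
  if (is.character(input) && !file.exists(input) && !dir.exists(input)) {
    stop("input `", input, "` does not exist", call. = FALSE)
  }
  if (is.character(calibration) && !file.exists(calibration)) {
    stop("calibration file `", calibration, "` does not exist",
         call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments; the
#' optional `blink:` mapping holds [blink_params()] fields.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$blink)) raw$blink <- do.call(blink_params, raw$blink)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

#' Run the full pupillometry workflow
#'
#' Executes the stages in their mandatory order: parse (or load) ->
#' blink reconstruction -> downsampling -> unit conversion -> baseline
#' correction -> trial exclusion -> data quality -> statistical test.
#' Every stage appends its parameters and counts to a run log; reruns with
#' an identical configuration and inputs produce identical artifacts. Any
#' stage failure aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the preprocessed `data`, the `qc` report,
#'   the `test` result, and the `log` lines. Artifacts are written under
#'   `config$output`: `preprocessed/` bundle, `qc.json`, `test.json`,
#'   `run_log.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- character()
  say <- function(...) logs <<- c(logs, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("pupilkit pipeline")
  say("stage order: parse -> reconstruct -> downsample -> convert -> ",
      "baseline -> exclude -> qc -> test")

  data <- stage("parse", {
    if (inherits(config$input, "trial_tbl")) {
      config$input
    } else if (dir.exists(config$input)) {
      read_bundle(config$input)
    } else {
      parse_asc(config$input)
    }
  })
  say("parse: ", nrow(data), " trials, series: ",
      paste(series_cols(data), collapse = ", "))
  pupil <- config$pupil

  raw <- data
  data <- stage("reconstruct", pp_reconstruct(data, pupil, config$blink))
  br <- attr(data, "blink_report")
  say("reconstruct: ", sum(br$n_blinks), " blinks; ", sum(br$n_cubic),
      " samples cubic, ", sum(br$n_linear), " linear; params: maxdur ",
      config$blink$maxdur_ms, " ms, blink margin ",
      config$blink$blink_margin_ms, " ms, gap margin ",
      config$blink$gap_margin_ms, " ms, outlier cut ",
      config$blink$std_thresh, " SD")

  if (config$downsample_factor > 1) {
    data <- stage("downsample", pp_downsample(data, config$downsample_factor))
    say("downsample: factor ", config$downsample_factor, ", new rate ",
        series_meta(data, pupil)$rate_hz, " Hz")
  } else {
    say("downsample: skipped (factor 1)")
  }

  if (!is.null(config$calibration)) {
    pairs <- if (is.character(config$calibration)) {
      readr::read_csv(config$calibration, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      config$calibration
    }
    model <- stage("convert", fit_calibration(pairs))
    data <- stage("convert", pp_convert(data, model, pupil))
    say("convert: ", model$form, " fit, coef ",
        paste(signif(model$coef, 6), collapse = ", "))
  } else {
    say("convert: skipped (no calibration)")
  }

  data <- stage("baseline", pp_baseline(data, config$baseline_window, pupil,
                                        config$baseline_mode))
  say("baseline: ", config$baseline_mode, " over [",
      config$baseline_window[1], ", ", config$baseline_window[2], ") ms")

  excl <- stage("exclude", exclude_baseline_outliers(
    data, paste0(pupil, "_baseline"), config$z_thresh))
  say("exclude: ", sum(!excl$keep), " of ", length(excl$keep),
      " trials (|z| > ", config$z_thresh, ")")
  kept <- excl$data

  qc <- stage("qc", qc_report(kept, raw = raw[excl$keep, ],
                              by = config$condition, col = pupil))
  say("qc: spike flag ", qc$flags$spikes, ", blink imbalance ",
      qc$flags$blink_imbalance)

  test <- stage("test", switch(
    config$method,
    window = window_test(kept, pupil, config$test_window,
                         config$condition, alpha = config$alpha),
    cluster = cluster_permutation_test(kept, pupil, config$condition,
                                       n_permutations = config$n_permutations,
                                       alpha = config$alpha,
                                       seed = config$seed),
    crossval = crossval_test(kept, pupil, config$condition,
                             n_folds = config$n_folds,
                             alpha = config$alpha)
  ))
  say("test: method ", config$method, ", alpha ", config$alpha)

  if (!dir.exists(config$output)) dir.create(config$output, recursive = TRUE)
  write_bundle(kept, file.path(config$output, "preprocessed"))
  jsonlite::write_json(
    list(per_participant = qc$per_participant, flags = qc$flags),
    file.path(config$output, "qc.json"), auto_unbox = TRUE, digits = NA)
  test_tbl <- switch(config$method,
                     window = as.data.frame(test),
                     cluster = as.data.frame(test$clusters),
                     crossval = as.data.frame(test$results))
  jsonlite::write_json(test_tbl, file.path(config$output, "test.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_lines(logs, file.path(config$output, "run_log.txt"))
  invisible(list(data = kept, qc = qc, test = test, log = logs))
}
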