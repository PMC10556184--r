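#' Fit a linear mixed-effects model to per-trial values
#'
#' Thin wrapper around [lme4::lmer()] producing a compact coefficient table
#' with Wald z statistics (`estimate / SE`) and two-tailed p-values from the
#' normal approximation, the convention used throughout the time-series
#' tests. No degrees-of-freedom correction is applied.
#'
#' @param data A data frame (or trial table) with one row per trial.
#' @param dv Name of the numeric dependent column; rows with missing values
#'   are dropped (the n actually used is reported).
#' @param fixed Character vector of fixed-effect terms (column names,
#'   interactions as `"a:b"`).
#' @param participant Name of the grouping column (default `"participant"`).
#' @param random `"intercept"` for by-participant random intercepts only,
#'   or `"slopes"` to add by-participant random slopes on the fixed effects.
#' @param alpha Significance level carried into the result (default .05).
#' @return A `pupil_fit`: a tibble with columns `term`, `estimate`, `se`,
#'   `z`, `p`, and attributes `converged`, `n_used`, `formula`.
#' @examples
#' d <- data.frame(participant = rep(c("a", "b", "c"), each = 20),
#'                 x = rnorm(60))
#' d$y <- 0.5 * d$x + rnorm(60)
#' fit_lmm(d, "y", "x")
#' @export
fit_lmm <- function(data, dv, fixed, participant = "participant",
                    random = c("intercept", "slopes"), alpha = 0.05) {
  random <- match.arg(random)
  stopifnot(alpha > 0, alpha < 1)
  grp <- data[[participant]]
  if (length(unique(grp)) < 2) {
    stop("need at least 2 participants: the random effect is undefined",
         call. = FALSE)
  }
  y <- data[[dv]]
  if (is.null(y)) stop("dependent column `", dv, "` not found", call. = FALSE)
  keep <- !is.na(y)
  if (!any(keep)) stop("dependent `", dv, "` has no non-missing values",
                       call. = FALSE)
  mains <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  d <- as.data.frame(data[keep, c(dv, mains, participant)])
  re <- if (random == "intercept") {
    sprintf("(1 | %s)", participant)
  } else {
    sprintf("(1 + %s | %s)", paste(mains, collapse = " + "), participant)
  }
  f <- stats::as.formula(paste0("`", dv, "` ~ ",
                                paste(fixed, collapse = " + "), " + ", re))
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(f, data = d, REML = TRUE),
      error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (inherits(fit, "error")) {
    out <- tibble::tibble(term = character(), estimate = numeric(),
                          se = numeric(), z = numeric(), p = numeric())
    attr(out, "converged") <- FALSE
    attr(out, "n_used") <- sum(keep)
    attr(out, "error") <- conditionMessage(fit)
    class(out) <- c("pupil_fit", class(out))
    return(out)
  }
  if (!is.null(fit@optinfo$conv$lme4$messages)) converged <- FALSE
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) {
    # degenerate fits (e.g. zero residual variance) can defeat the
    # covariance extraction; fall back to the package's own
    # random-intercept REML fitter on the same rows
    des <- ri_design(d, fixed, participant)
    rf <- ri_lmm_fit(matrix(d[[dv]], ncol = 1), des$X, des$g, des$G)
    co <- cbind(rf$beta[, 1], rf$se[, 1], rf$beta[, 1] / rf$se[, 1])
    rownames(co) <- des$terms
    colnames(co) <- c("Estimate", "Std. Error", "t value")
    converged <- FALSE
  }
  out <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    z = unname(co[, "t value"]),
    p = unname(2 * stats::pnorm(-abs(co[, "t value"])))
  )
  attr(out, "converged") <- converged
  attr(out, "n_used") <- nrow(d)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "formula") <- deparse(f)
  attr(out, "alpha") <- alpha
  class(out) <- c("pupil_fit", class(out))
  out
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat("Linear mixed-effects fit (Wald z, normal-approximation p)\n")
  if (!is.null(attr(x, "formula"))) cat("  ", attr(x, "formula"), "\n")
  cat("  n =", attr(x, "n_used"),
      if (isFALSE(attr(x, "converged"))) " [did not converge]" else "", "\n")
  NextMethod()
}

# design matrix + grouping for the fast per-sample engine
ri_design <- function(data, fixed, participant) {
  mains <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  X <- stats::model.matrix(stats::reformulate(fixed),
                           data = as.data.frame(data[, mains, drop = FALSE]))
  grp <- as.factor(as.character(data[[participant]]))
  list(X = X, g = as.integer(grp) - 1L, G = nlevels(grp),
       terms = colnames(X))
}

#' Per-sample mixed-effects tests along a pupil time series
#'
#' Fits one model per time sample of a series column: the dependent is the
#' pupil size at that sample across trials. The default engine is a
#' profiled-REML random-intercept fitter (compiled; identical model to
#' `lmer(y ~ fixed + (1 | participant))`) which makes per-sample scans and
#' permutation schemes affordable; `engine = "lmer"` runs lme4 per sample
#' and is provided for cross-checking at small scale.
#'
#' @inheritParams fit_lmm
#' @param dv Name of the series (matrix) column to scan.
#' @param engine `"fast"` (default) or `"lmer"`.
#' @return A tibble with one row per sample x term: `sample` (0-based),
#'   `time_ms`, `term`, `estimate`, `se`, `z`, `p`, `n_used`. Samples where
#'   the fit fails carry `NA`.
#' @export
persample_tests <- function(data, dv, fixed, participant = "participant",
                            engine = c("fast", "lmer")) {
  engine <- match.arg(engine)
  meta <- series_meta(data, dv)
  Y <- data[[dv]]
  n_s <- ncol(Y)
  dt <- 1000 / meta$rate_hz
  des <- ri_design(data, fixed, participant)
  if (engine == "fast") {
    fit <- ri_lmm_fit(Y, des$X, des$g, des$G)
    out <- tidyr::expand_grid(sample = seq_len(n_s) - 1L, term = des$terms)
    # fit$beta is terms x samples; column-major flattening matches the
    # sample-major, term-fastest row order of expand_grid
    out$estimate <- as.vector(fit$beta)
    out$se <- as.vector(fit$se)
    out$n_used <- rep(fit$n_used, each = length(des$terms))
  } else {
    rows <- purrr::map(seq_len(n_s), function(j) {
      d2 <- data
      d2$.sample_dv <- Y[, j]
      ft <- tryCatch(
        suppressWarnings(fit_lmm(d2, ".sample_dv", fixed, participant,
                                 random = "intercept")),
        error = function(e) NULL)
      if (is.null(ft) || nrow(ft) == 0) {
        tibble::tibble(sample = j - 1L, term = des$terms,
                       estimate = NA_real_, se = NA_real_,
                       n_used = NA_integer_)
      } else {
        tibble::tibble(sample = j - 1L, term = ft$term,
                       estimate = ft$estimate, se = ft$se,
                       n_used = attr(ft, "n_used"))
      }
    })
    out <- dplyr::bind_rows(rows)
  }
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$time_ms <- meta$t0_ms + out$sample * dt
  out[, c("sample", "time_ms", "term", "estimate", "se", "z", "p", "n_used")]
}
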