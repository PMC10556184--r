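#' Test mean pupil size in a predetermined time window
#'
#' Averages the dependent series over the window (per trial, ignoring
#' missing) and fits a single linear mixed-effects model to the per-trial
#' means. Because only one test is conducted, no multiple-comparison
#' correction is needed; the price is that the window must be chosen before
#' seeing the data.
#'
#' @inheritParams fit_lmm
#' @param dv Name of the series (matrix) column.
#' @param window A [time_window()] or `c(start_ms, end_ms)` within the epoch.
#' @return A `pupil_fit` (see [fit_lmm()]) with a `window` attribute; trials
#'   whose window is all-missing are dropped and counted in `n_dropped`.
#' @export
window_test <- function(data, dv, window, fixed,
                        participant = "participant",
                        random = c("slopes", "intercept"), alpha = 0.05) {
  random <- match.arg(random)
  idx <- window_cols(data, dv, window)
  y <- rowMeans(data[[dv]][, idx, drop = FALSE], na.rm = TRUE)
  y[is.nan(y)] <- NA_real_
  d <- data
  d$.window_mean <- y
  out <- fit_lmm(d, ".window_mean", fixed, participant, random, alpha)
  attr(out, "window") <- as_time_window(window)
  out
}

#' Find clusters of contiguous significant samples
#'
#' A cluster is a maximal run of contiguous samples with `p < alpha` and a
#' constant sign of z; a sign flip splits the run. Cluster size is the run
#' length in samples.
#'
#' @param p,z Aligned numeric vectors of per-sample p-values and z-values.
#' @param alpha Significance level (default .05).
#' @return A tibble with one row per cluster: `start` and `end` (0-based,
#'   half-open `[start, end)`), `size`, `sign`.
#' @export
find_clusters <- function(p, z, alpha = 0.05) {
  stopifnot(length(p) == length(z))
  sig <- !is.na(p) & p < alpha
  key <- ifelse(sig, sign(z), 0)
  key[is.na(key)] <- 0
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values != 0)
  tibble::tibble(
    start = starts[i] - 1L,
    end = ends[i],
    size = r$lengths[i],
    sign = r$values[i]
  )
}

#' Cluster-based permutation test for a pupil time series
#'
#' Controls the family-wise error rate over an autocorrelated time series.
#' Per-sample tests on the observed data give clusters of contiguous
#' significant samples; the labels of the tested effect are then shuffled
#' within participant `n_permutations` times, the per-sample analysis is
#' re-run each time, and the maximum false-alarm cluster size per
#' permutation forms the null distribution. Each observed cluster's p-value
#' is `(1 + #\{null >= size\}) / (1 + n_permutations)`, so it is never
#' smaller than `1 / (n_permutations + 1)`.
#'
#' @inheritParams persample_tests
#' @param effect The fixed-effect column whose labels are shuffled (the
#'   model's only fixed effect here).
#' @param n_permutations Number of label shuffles (>= 100; default 1000).
#' @param alpha Per-sample significance level for cluster formation.
#' @param seed Integer seed making the shuffle sequence reproducible.
#' @param engine Per-sample engine: `"fast"` (random-intercept mixed model,
#'   compiled) or `"aggregate"` (per-participant regression slope tested
#'   across participants by a one-sample t-test; faster, aggregated).
#' @param null_stat `"max"` (default): null distribution of the maximum
#'   cluster size per permutation (family-wise control); `"all"`: pool every
#'   false-alarm cluster size across permutations.
#' @return A `pupil_clusterperm` object: observed per-sample `tests`
#'   (tibble), `clusters` (with per-cluster `p_cluster`), `null_max` sizes,
#'   `n_permutations`, `seed`.
#' @export
cluster_permutation_test <- function(data, dv, effect,
                                     participant = "participant",
                                     n_permutations = 1000, alpha = 0.05,
                                     seed = 1,
                                     engine = c("fast", "aggregate"),
                                     null_stat = c("max", "all")) {
  engine <- match.arg(engine)
  null_stat <- match.arg(null_stat)
  stopifnot(n_permutations >= 100)
  x <- data[[effect]]
  if (!is.numeric(x) && !is.factor(x) && !is.character(x)) {
    stop("effect `", effect, "` cannot be shuffled", call. = FALSE)
  }
  if (is.character(x)) {
    stop("effect `", effect, "` is character; use a numeric coding ",
         "(e.g. -1/0/1) or a factor", call. = FALSE)
  }
  Y <- data[[dv]]
  meta <- series_meta(data, dv)
  grp <- as.factor(as.character(data[[participant]]))

  zp <- function(xvals) {
    if (engine == "fast") {
      X <- cbind(1, as.numeric(xvals))
      fit <- ri_lmm_fit(Y, X, as.integer(grp) - 1L, nlevels(grp))
      z <- fit$beta[2, ] / fit$se[2, ]
    } else {
      z <- aggregate_slope_z(Y, as.numeric(xvals), grp)
    }
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
  }

  obs <- zp(x)
  clusters <- find_clusters(obs$p, obs$z, alpha)

  idx_by_grp <- split(seq_along(x), grp)
  withr::local_seed(seed)
  null_max <- numeric(n_permutations)
  null_all <- list()
  for (b in seq_len(n_permutations)) {
    xs <- x
    for (idx in idx_by_grp) xs[idx] <- x[sample(idx)]
    perm <- zp(xs)
    cl <- find_clusters(perm$p, perm$z, alpha)
    null_max[b] <- if (nrow(cl)) max(cl$size) else 0
    if (null_stat == "all") null_all[[b]] <- cl$size
  }
  null_sizes <- if (null_stat == "max") null_max else
    unlist(null_all, use.names = FALSE)
  denom <- if (null_stat == "max") n_permutations else
    max(1L, length(null_sizes))
  clusters$p_cluster <- vapply(clusters$size, function(s) {
    (1 + sum(null_sizes >= s)) / (1 + denom)
  }, numeric(1))

  dt <- 1000 / meta$rate_hz
  tests <- tibble::tibble(
    sample = seq_along(obs$z) - 1L,
    time_ms = meta$t0_ms + (seq_along(obs$z) - 1L) * dt,
    z = obs$z, p = obs$p
  )
  structure(list(tests = tests, clusters = clusters, null_max = null_max,
                 n_permutations = n_permutations, alpha = alpha,
                 seed = seed, effect = effect, engine = engine,
                 null_stat = null_stat, rate_hz = meta$rate_hz,
                 t0_ms = meta$t0_ms),
            class = "pupil_clusterperm")
}

# per-participant OLS slope of y on x, tested across participants with a
# one-sample t; vectorized over samples
aggregate_slope_z <- function(Y, x, grp) {
  G <- nlevels(grp)
  z <- rep(NA_real_, ncol(Y))
  slopes <- matrix(NA_real_, G, ncol(Y))
  for (gi in seq_len(G)) {
    i <- which(as.integer(grp) == gi)
    xi <- x[i]
    vx <- stats::var(xi)
    if (is.na(vx) || vx == 0) next
    Yi <- Y[i, , drop = FALSE]
    xc <- xi - mean(xi)
    # missing-aware per-sample covariance
    ok <- !is.na(Yi)
    Y0 <- ifelse(ok, Yi, 0)
    sxy <- colSums(Y0 * xc)
    sx2 <- colSums(ok * xc^2)
    slopes[gi, ] <- ifelse(sx2 > 0, sxy / sx2, NA_real_)
  }
  m <- colMeans(slopes, na.rm = TRUE)
  s <- apply(slopes, 2, stats::sd, na.rm = TRUE)
  k <- colSums(!is.na(slopes))
  t_stat <- m / (s / sqrt(k))
  # map the t onto the standard-normal scale used everywhere else
  tail <- stats::pt(abs(t_stat), df = pmax(1, k - 1), lower.tail = FALSE)
  sign(t_stat) * -stats::qnorm(tail)
}

#' @export
print.pupil_clusterperm <- function(x, ...) {
  cat("Cluster-based permutation test on `", x$effect, "` (",
      x$n_permutations, " permutations, within-participant shuffling, ",
      x$engine, " engine)\n", sep = "")
  if (nrow(x$clusters) == 0) {
    cat("  no cluster of samples with p <", x$alpha,
        "in the observed data (p = 1)\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Deterministic interleaved fold assignment
#'
#' Row `i` (1-based) is assigned to the test set of fold
#' `((i - 1) mod n_folds) + 1`: with four folds, three consecutive rows go
#' to the training set and the next row to the test set, cycling so that the
#' folds' test sets partition the rows and each fold trains on exactly
#' `(n_folds - 1) / n_folds` of the data. Splitting ignores how conditions
#' are distributed across rows; it is a pure function of the row order.
#'
#' @param n_rows Number of rows (>= `n_folds`).
#' @param n_folds Number of folds (default 4).
#' @return Integer vector of fold ids in `1:n_folds`, one per row.
#' @export
interleaved_split <- function(n_rows, n_folds = 4) {
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (n_rows < n_folds) stop("need at least as many rows as folds",
                             call. = FALSE)
  ((seq_len(n_rows) - 1L) %% as.integer(n_folds)) + 1L
}

#' Cross-validation test for a pupil time series
#'
#' Avoids circular "look then test" inference on a time series without
#' giving up single-trial mixed-effects modelling. The rows are split into
#' `n_folds` interleaved folds. For each fold, per-sample random-intercept
#' models on the training rows localize, per fixed effect, the sample with
#' the largest |z| (ties break to the lowest index); that sample becomes the
#' tested sample for the fold's held-out rows. A single final mixed model
#' (with the requested random structure) is then fitted to each trial's own
#' tested-sample value, so the dependent mixes sample indices across trials
#' but no trial contributed to choosing its own sample. The procedure is
#' repeated independently for each main effect and interaction, and is fully
#' deterministic: no randomness enters at any point.
#'
#' @inheritParams fit_lmm
#' @param dv Name of the series (matrix) column.
#' @param n_folds Number of interleaved folds (default 4).
#' @param random Random structure of the final model: `"slopes"` (default,
#'   by-participant random intercepts and slopes) or `"intercept"`.
#'   Localization always uses random intercepts only.
#' @return A `pupil_cvtest` object: `results` (one row per effect: estimate,
#'   se, z, p, n_used, n_dropped), `chosen` (effect x fold matrix of 0-based
#'   tested sample indices), `folds` (fold id per row), `alpha`.
#' @export
crossval_test <- function(data, dv, fixed, participant = "participant",
                          n_folds = 4, random = c("slopes", "intercept"),
                          alpha = 0.05) {
  random <- match.arg(random)
  meta <- series_meta(data, dv)
  Y <- data[[dv]]
  n <- nrow(Y)
  folds <- interleaved_split(n, n_folds)
  des <- ri_design(data, fixed, participant)
  terms <- setdiff(des$terms, "(Intercept)")
  if (length(terms) == 0) stop("no fixed effect to test", call. = FALSE)

  chosen <- matrix(NA_integer_, length(terms), n_folds,
                   dimnames = list(terms, NULL))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (length(unique(des$g[tr])) < 2) {
      stop("fold ", k, " training set has fewer than 2 participants",
           call. = FALSE)
    }
    grp_tr <- as.integer(factor(des$g[tr])) - 1L
    fit <- ri_lmm_fit(Y[tr, , drop = FALSE], des$X[tr, , drop = FALSE],
                      grp_tr, length(unique(grp_tr)))
    zmat <- abs(fit$beta / fit$se)   # terms x samples
    for (tm in terms) {
      zrow <- zmat[match(tm, des$terms), ]
      if (all(!is.finite(zrow))) {
        stop("fold ", k, ": no sample could be localized for effect `",
             tm, "`", call. = FALSE)
      }
      chosen[tm, k] <- which.max(replace(zrow, !is.finite(zrow), -Inf)) - 1L
    }
  }

  res <- purrr::map(terms, function(tm) {
    yv <- Y[cbind(seq_len(n), chosen[tm, folds] + 1L)]
    d <- data
    d$.cv_dv <- yv
    ft <- fit_lmm(d, ".cv_dv", fixed, participant, random, alpha)
    row <- ft[ft$term == tm, ]
    if (nrow(row) == 0) {
      row <- tibble::tibble(term = tm, estimate = NA_real_, se = NA_real_,
                            z = NA_real_, p = NA_real_)
    }
    row$n_used <- attr(ft, "n_used")
    row$n_dropped <- attr(ft, "n_dropped") %||% 0L
    row$converged <- attr(ft, "converged")
    row
  })
  results <- dplyr::bind_rows(res)

  structure(list(results = results, chosen = chosen, folds = folds,
                 alpha = alpha, dv = dv, fixed = fixed, random = random,
                 rate_hz = meta$rate_hz, t0_ms = meta$t0_ms),
            class = "pupil_cvtest")
}

#' @export
print.pupil_cvtest <- function(x, ...) {
  dt <- 1000 / x$rate_hz
  cat("Cross-validation test on `", x$dv, "` (", length(unique(x$folds)),
      "-fold interleaved split; final random structure: ", x$random,
      ")\n", sep = "")
  for (tm in rownames(x$chosen)) {
    cat("  ", tm, ": tested at sample(s) ",
        paste(sort(unique(x$chosen[tm, ])), collapse = ", "),
        " (", paste(round(x$t0_ms + sort(unique(x$chosen[tm, ])) * dt),
                    collapse = ", "), " ms)\n", sep = "")
  }
  print(x$results)
  invisible(x)
}
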