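test_that("downsampling is block-mean with missing-aware semantics", {
  x <- rnorm(3000)
  y <- downsample(x, 10)
  expect_length(y, 300)
  expect_equal(downsample(x, 1), x)
  expect_equal(downsample(c(1, 1, 3, 3), 2), c(1, 3))
  expect_equal(downsample(c(2, NA), 2), 2)
  expect_equal(downsample(c(NA, NA, 1, 2), 2), c(NA, 1.5))
  expect_error(downsample(x, 0), "positive integer")
  expect_error(downsample(x, 2.5), "positive integer")
  # trailing partial block dropped
  expect_length(downsample(rnorm(25), 10), 2)
  # mean conserved on fully valid traces of multiple length
  expect_equal(mean(downsample(x, 10)), mean(x))
  # matrix form divides the rate via the table verb
  tt <- toy_table()
  out <- pp_downsample(tt, 5)
  expect_equal(ncol(out$pupil), 1)
  expect_equal(series_meta(out, "pupil")$rate_hz, 20)
})

test_that("power-law calibration recovers generating parameters", {
  set.seed(2)
  u <- seq(800, 3000, length.out = 15)
  pairs <- data.frame(units = u, mm = 0.05 * u^0.5 * exp(rnorm(15, 0, 1e-3)))
  m <- fit_calibration(pairs)
  expect_lt(abs(m$coef[["a"]] - 0.05) / 0.05, 0.01)
  expect_lt(abs(m$coef[["b"]] - 0.5) / 0.5, 0.01)
  # identity data: predictions equal inputs within fit tolerance
  ident <- data.frame(units = 1:15, mm = 1:15)
  mi <- fit_calibration(ident)
  expect_equal(predict(mi, 1:15), as.numeric(1:15), tolerance = 1e-6)
  expect_error(fit_calibration(data.frame(units = 1:2, mm = 1:2)),
               "at least 3")
  expect_error(fit_calibration(data.frame(units = rep(2, 5), mm = rep(3, 5))),
               "zero variance")
  expect_error(fit_calibration(data.frame(units = c(-1, 1, 2), mm = 1:3)),
               "positive")
})

test_that("unit conversion is elementwise, invertible, and NA-preserving", {
  u <- seq(500, 3000, length.out = 12)
  m <- fit_calibration(data.frame(units = u, mm = 0.05 * u^0.5))
  tt <- trial_table(data.frame(participant = "a"),
                    list(pupil = matrix(c(900, NA, 1600, 2500), 1)),
                    rate_hz = 100)
  out <- pp_convert(tt, m)
  expect_true(is.na(out$pupil[1, 2]))
  # closed-form inverse of the power law recovers the input
  back <- (out$pupil[1, c(1, 3, 4)] / m$coef[["a"]])^(1 / m$coef[["b"]])
  expect_equal(back, tt$pupil[1, c(1, 3, 4)], tolerance = 1e-8)
  # out-of-range input warns but still converts
  tt2 <- trial_table(data.frame(participant = "a"),
                     list(pupil = matrix(c(100, 900), 1)), rate_hz = 100)
  expect_warning(pp_convert(tt2, m), "calibrated range")
})

test_that("baseline correction matches the stated identities", {
  m <- matrix(c(4, 4, 6, 8), 1)
  sub <- baseline_correct(m, 1:2, "subtractive")
  expect_equal(as.vector(sub$values), c(0, 0, 2, 4))
  expect_equal(sub$baseline, 4)
  div <- baseline_correct(m, 1:2, "divisive")
  expect_equal(as.vector(div$values), c(1, 1, 1.5, 2))
  # all-missing window: whole trial missing, baseline missing
  m2 <- rbind(c(NA, NA, 5, 6), c(1, 3, 5, 7))
  res <- baseline_correct(m2, 1:2)
  expect_true(all(is.na(res$values[1, ])))
  expect_true(is.na(res$baseline[1]))
  expect_equal(res$values[2, ], c(-1, 1, 3, 5))
  # divisive with zero baseline: trial missing with a warning
  m3 <- rbind(c(0, 0, 2, 2))
  expect_warning(r3 <- baseline_correct(m3, 1:2, "divisive"), "0")
  expect_true(all(is.na(r3$values)))
})

test_that("subtractive correction zeroes the baseline window on every trial", {
  sim <- simulate_dataset(reduced_spec(6, n_participants = 3,
                                       trials_per_participant = 10,
                                       blink_rate = 1))
  d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
  idx <- 1:5  # [0, 50) ms at 100 Hz
  bw_mean <- rowMeans(d$pupil[, idx], na.rm = TRUE)
  ok <- !is.na(d$pupil_baseline)
  expect_true(all(abs(bw_mean[ok]) < 1e-9))
})

test_that("baseline z-score exclusion works within participant", {
  d <- tibble::tibble(participant = rep("a", 10))
  b <- c(rep(0, 9), 10)
  res <- exclude_baseline_outliers(d, b, z_thresh = 2)
  # sample-SD z-scores: only the aberrant trial exceeds |z| > 2
  expect_equal(which(!res$keep), 10)
  expect_equal(res$counts$n_excluded, 1)
  # all-equal baselines: zero variance, none excluded, warning
  expect_warning(r2 <- exclude_baseline_outliers(d, rep(5, 10)), "zero")
  expect_true(all(r2$keep))
  # missing baselines are excluded and counted
  r3 <- exclude_baseline_outliers(d, c(rnorm(9), NA))
  expect_false(r3$keep[10])
  expect_error(exclude_baseline_outliers(d, c(NA, rnorm(8), NA)[1:9]),
               "align")
})

test_that("exclusion fraction matches the Gaussian tail at scale", {
  set.seed(99)
  n <- 20000
  d <- tibble::tibble(participant = rep(sprintf("p%d", 1:4), each = n / 4))
  res <- exclude_baseline_outliers(d, rnorm(n), z_thresh = 2)
  frac <- mean(!res$keep)
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.004)
})

test_that("the preprocessing chain enforces its stage order", {
  sim <- simulate_dataset(reduced_spec(8, n_participants = 2,
                                       trials_per_participant = 4))
  d <- pp_downsample(sim$data, 10)
  expect_error(pp_reconstruct(d, "pupil"), "out of order")
  d <- pp_baseline(d, c(0, 50))
  expect_error(pp_downsample(d, 2), "out of order")
  u <- seq(500, 3000, length.out = 10)
  m <- fit_calibration(data.frame(units = u, mm = 0.05 * u^0.5))
  expect_error(pp_convert(d, m), "out of order")
})
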