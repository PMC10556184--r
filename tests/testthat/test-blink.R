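# a smooth synthetic epoch with one injected blink and its pre-injection
# oracle
blink_fixture <- function(seed = 1, dur_ms = 200, onset = 1200, n = 3000) {
  set.seed(seed)
  t <- seq_len(n) - 1
  clean <- 1800 + 60 * sin(2 * pi * (t + runif(1, 0, 10000)) / 10000) +
    50 * response_kernel(t - 750) + rnorm(n, 0, 1)
  x <- clean
  ramp <- 10
  down <- onset:(onset + ramp - 1)
  gap <- (onset + ramp):(onset + ramp + dur_ms - 1)
  up <- (onset + ramp + dur_ms):(onset + 2 * ramp + dur_ms - 1)
  rr <- seq(1, 0, length.out = ramp + 1)[1:ramp]
  x[down] <- clean[onset] * rr
  x[gap] <- NA
  x[up] <- clean[max(up) + 1] * rev(rr)
  list(x = x, clean = clean, extent = c(min(down), max(up)))
}

test_that("a 200 ms blink is reconstructed close to the oracle trace", {
  f <- blink_fixture(1)
  res <- reconstruct_blinks(f$x, 1000)
  idx <- f$extent[1]:f$extent[2]
  err <- max(abs(res$values[idx] - f$clean[idx]), na.rm = TRUE)
  expect_lt(err, 0.05 * diff(range(f$clean)))
  expect_gt(res$report$n_cubic, 0)   # spline path was used
  expect_equal(res$report$n_blinks >= 1, TRUE)
  # no missing data remains inside the blink extent
  expect_false(anyNA(res$values[idx]))
})

test_that("blink-like gaps longer than maxdur are never interpolated", {
  f <- blink_fixture(2, dur_ms = 600)
  res <- reconstruct_blinks(f$x, 1000)
  gap <- (f$extent[1] + 30):(f$extent[2] - 30)
  expect_true(all(is.na(res$values[gap])))
})

test_that("a constant trace passes through identically", {
  x <- rep(1500, 1000)
  res <- reconstruct_blinks(x, 1000)
  expect_identical(res$values, x)
  expect_equal(res$report$n_blinks, 0L)
})

test_that("a blink at the start of the trace is handled without error", {
  f <- blink_fixture(3)
  # cut the trace so it begins mid-closing-ramp: no pre-onset anchors exist
  x <- f$x[(f$extent[1] + 3):length(f$x)]
  expect_silent(res <- reconstruct_blinks(x, 1000))
  # onset-side samples stay missing up to the first valid anchor
  expect_true(anyNA(res$values[1:50]))
})

test_that("degenerate traces are reported as specified", {
  expect_warning(res <- reconstruct_blinks(rep(NA_real_, 100), 1000),
                 "all-missing")
  expect_true(res$report$all_missing)
  expect_error(reconstruct_blinks(c(1, 2, 3), 1000), "shorter")
  expect_error(blink_params(maxdur_ms = 15, blink_margin_ms = 10))
})

test_that("valid data away from blinks is returned bit-identical", {
  sim <- simulate_dataset(synthetic_spec(n_participants = 2,
                                         trials_per_participant = 8,
                                         seed = 21))
  rec <- pp_reconstruct(sim$data, "pupil")
  bl <- sim$truth$blinks
  clean_rows <- setdiff(seq_len(nrow(sim$data)), bl$row)
  expect_identical(rec$pupil[clean_rows, ], sim$data$pupil[clean_rows, ])
  # rows with blinks: samples far from any blink extent are untouched
  for (r in unique(bl$row)) {
    br <- bl[bl$row == r, ]
    far <- setdiff(seq_len(ncol(rec$pupil)),
                   unlist(lapply(seq_len(nrow(br)), function(i) {
                     max(1, br$onset_sample[i] - 60):
                       min(ncol(rec$pupil), br$end_sample[i] + 62)
                   })))
    expect_identical(rec$pupil[r, far], sim$data$pupil[r, far])
  }
})

test_that("reconstruction is idempotent on simulator output", {
  for (seed in c(4, 9)) {
    sim <- simulate_dataset(synthetic_spec(n_participants = 2,
                                           trials_per_participant = 10,
                                           seed = seed))
    rec <- pp_reconstruct(sim$data, "pupil")
    rec_tbl <- rec
    attr(rec_tbl, "pp_stage") <- NULL
    rec2 <- pp_reconstruct(rec_tbl, "pupil")
    expect_identical(rec2$pupil, rec$pupil)
  }
})

test_that("median reconstruction error stays below 5% of dynamic range", {
  sim <- simulate_dataset(synthetic_spec(n_participants = 4,
                                         trials_per_participant = 12,
                                         seed = 31))
  rec <- pp_reconstruct(sim$data, "pupil")
  bl <- sim$truth$blinks
  single <- as.integer(names(which(table(bl$row) == 1)))
  rel <- vapply(single, function(r) {
    b <- bl[bl$row == r, ]
    idx <- (b$onset_sample + 1):(b$end_sample + 1)
    e <- abs(rec$pupil[r, idx] - sim$truth$clean[r, idx])
    max(e, na.rm = TRUE) / diff(range(sim$truth$clean[r, ]))
  }, numeric(1))
  expect_lt(median(rel), 0.05)
})
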