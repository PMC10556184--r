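test_that("spike detection flags exactly the injected trials", {
  sim <- simulate_dataset(reduced_spec(14, n_participants = 5,
                                       trials_per_participant = 20))
  d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
  clean <- spike_trials(d$pupil)
  expect_equal(clean$fraction, 0)

  inj <- inject_spikes(d, fraction = 0.07, magnitude = 500, seed = 4)
  sp <- spike_trials(inj$data$pupil)
  expect_equal(which(sp$spike), inj$rows)
  expect_equal(sp$fraction, 0.07)

  expect_error(spike_trials(d$pupil[1:2, ]), "at least 3")
})

test_that("spike detection stays silent on clean data across seeds", {
  for (seed in 101:115) {
    sim <- simulate_dataset(reduced_spec(seed, n_participants = 3,
                                         trials_per_participant = 10))
    d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
    expect_equal(spike_trials(d$pupil)$fraction, 0)
  }
})

test_that("blink counts from the missing-run proxy track the injection rate", {
  sim <- simulate_dataset(synthetic_spec(n_participants = 5,
                                         trials_per_participant = 40,
                                         blink_rate = 1, seed = 16))
  bc <- blink_counts(sim$data, by = "ecc")
  n_inj <- nrow(sim$truth$blinks)
  grand <- mean(bc$per_trial)
  # grand mean within 3 SE of the Poisson rate
  expect_lt(abs(grand - 1), 3 * sqrt(1 / nrow(sim$data)) + abs(1 - n_inj / nrow(sim$data)))
  expect_false(bc$imbalance)

  # zero injected blinks: all counts 0
  sim0 <- simulate_dataset(reduced_spec(17, n_participants = 2,
                                        trials_per_participant = 6))
  bc0 <- blink_counts(sim0$data, by = "ecc")
  expect_true(all(bc0$per_trial == 0))
})

test_that("condition-dependent blink rates raise the imbalance flag", {
  set.seed(5)
  n <- 200
  d <- tibble::tibble(participant = rep(c("a", "b"), each = n / 2),
                      cond = rep(c("x", "y"), n / 2))
  lam <- ifelse(d$cond == "x", 0.5, 1.5)
  events <- tibble::tibble(
    row = rep(seq_len(n), times = rpois(n, lam))
  )
  d <- trial_table(d, list(pupil = matrix(rnorm(n * 10), n)), rate_hz = 100)
  bc <- blink_counts(d, by = "cond", events = events)
  expect_true(bc$imbalance)
})

test_that("gaze deviation converts to degrees and averages by condition", {
  n <- 20; S <- 30
  cx <- c(512, 384); ppd <- 35
  scal <- tibble::tibble(participant = "a",
                         cond = rep(c("near", "far"), each = n / 2))
  gx <- matrix(cx[1], n, S); gy <- matrix(cx[2], n, S)
  # one condition offset by exactly 1 degree horizontally
  gx[scal$cond == "far", ] <- cx[1] + ppd
  d <- trial_table(scal, list(gaze_x = gx, gaze_y = gy), rate_hz = 100)
  gd <- gaze_deviation(d, "cond", center_px = cx, px_per_degree = ppd)
  expect_equal(unique(gd$h_deg[gd$condition == "near"]), 0)
  expect_equal(unique(gd$h_deg[gd$condition == "far"]), 1)
  expect_true(all(gd$v_deg == 0))
})

test_that("gaze noise yields the folded-normal mean deviation", {
  sim <- simulate_dataset(synthetic_spec(n_participants = 4,
                                         trials_per_participant = 30,
                                         rate_hz = 100, epoch_ms = 1000,
                                         effect_window = c(260, 900),
                                         kernel_tpeak_ms = 300,
                                         blink_rate = 0, seed = 18))
  gd <- gaze_deviation(sim$data, "ecc", center_px = c(512, 384),
                       px_per_degree = 35)
  # E|N(0, 0.3)| = 0.3 * sqrt(2 / pi)
  expect_equal(mean(gd$h_deg), 0.3 * sqrt(2 / pi), tolerance = 0.05)
  expect_equal(mean(gd$v_deg), 0.3 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("the aggregate QC report collects metrics and flags", {
  sim <- simulate_dataset(reduced_spec(19, n_participants = 3,
                                       trials_per_participant = 20,
                                       blink_rate = 0.5))
  raw <- sim$data
  d <- pp_baseline(pp_downsample(pp_reconstruct(raw, "pupil"), 10), c(0, 50))
  qc <- qc_report(d, raw = raw, by = "ecc", center_px = c(512, 384),
                  px_per_degree = 35)
  expect_s3_class(qc$per_participant, "tbl_df")
  expect_equal(nrow(qc$per_participant), 3)
  expect_false(qc$flags$spikes)
  expect_true(all(qc$per_participant$spike_fraction >= 0 &
                    qc$per_participant$spike_fraction <= 1))
  expect_true(all(qc$per_participant$missing_fraction >= 0 &
                    qc$per_participant$missing_fraction <= 1))

  # inject many spikes: flag goes up
  inj <- inject_spikes(d, fraction = 0.10, magnitude = 800, seed = 7)
  qc2 <- qc_report(inj$data, raw = raw, by = "ecc")
  expect_true(qc2$flags$spikes)

  # error without baseline column
  expect_error(qc_report(pp_downsample(sim$data, 10), by = "ecc"),
               "pp_baseline")
})

test_that("QC metrics are invariant to trial order within participant", {
  sim <- simulate_dataset(reduced_spec(20, n_participants = 2,
                                       trials_per_participant = 12,
                                       blink_rate = 1))
  d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
  set.seed(1)
  perm <- unlist(lapply(split(seq_len(nrow(d)), d$participant), sample))
  d2 <- d[perm, ]
  q1 <- spike_trials(d$pupil)$fraction
  q2 <- spike_trials(d2$pupil)$fraction
  expect_equal(q1, q2)
  b1 <- blink_counts(sim$data, by = "ecc")$counts
  b2 <- blink_counts(sim$data[perm, ], by = "ecc")$counts
  expect_equal(dplyr::arrange(b1, participant, condition),
               dplyr::arrange(b2, participant, condition))
})
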