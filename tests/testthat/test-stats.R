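test_that("the window test detects a window-confined effect", {
  sim <- simulate_dataset(reduced_spec(25, n_participants = 10,
                                       trials_per_participant = 21,
                                       effect_size = 50, slope_sd = 10,
                                       condition_values = c(near = -1,
                                                            medium = 0,
                                                            far = 1)))
  d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
  ft <- window_test(d, "pupil", c(260, 500), "ecc_code")
  row <- ft[ft$term == "ecc_code", ]
  expect_lt(row$p, 0.05)
  expect_gt(row$estimate, 0)
  # a window before the effect carries no signal (may rarely reach .05;
  # assert the estimate is small rather than the p-value)
  ft0 <- window_test(d, "pupil", c(50, 250), "ecc_code")
  expect_lt(abs(ft0$estimate[ft0$term == "ecc_code"]),
            abs(row$estimate))
  expect_error(window_test(d, "pupil", c(900, 1200), "ecc_code"), "overlap")
})

test_that("trials with an all-missing window are dropped and counted", {
  tt <- trial_table(
    data.frame(participant = rep(c("a", "b"), each = 4), x = rnorm(8)),
    list(pupil = rbind(matrix(rnorm(28), 7, 4), rep(NA_real_, 4))),
    rate_hz = 100
  )
  ft <- suppressWarnings(window_test(tt, "pupil", c(0, 40), "x"))
  expect_equal(attr(ft, "n_used"), 7)
  expect_equal(attr(ft, "n_dropped"), 1)
})

test_that("cluster finding respects alpha and sign changes", {
  cl <- find_clusters(c(.2, .01, .01, .2), c(1, 2, 2, 1))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 2)
  expect_equal(cl$start, 1)
  expect_equal(cl$end, 3)
  # nothing below alpha: empty
  expect_equal(nrow(find_clusters(rep(.5, 10), rnorm(10))), 0)
  # a sign flip inside a sub-alpha run splits the cluster
  cl2 <- find_clusters(c(.01, .01, .01, .01), c(2, 2, -2, -2))
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$size, c(2, 2))
  expect_equal(cl2$sign, c(1, -1))
  # missing p-values break runs without erroring
  cl3 <- find_clusters(c(.01, NA, .01), c(2, NA, 2))
  expect_equal(nrow(cl3), 2)
})

test_that("interleaved splitting partitions rows deterministically", {
  f <- interleaved_split(8, 4)
  expect_equal(f, c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L))
  # fold 4's test rows are rows 4 and 8
  expect_equal(which(f == 4), c(4, 8))
  # each fold trains on exactly 75% when n is a multiple of 4
  for (n in c(8, 40, 100)) {
    f <- interleaved_split(n, 4)
    expect_true(all(table(f) == n / 4))
    expect_equal(sort(unlist(lapply(1:4, function(k) which(f == k)))),
                 seq_len(n))
  }
  expect_error(interleaved_split(10, 1), "at least 2")
  expect_error(interleaved_split(2, 4), "at least as many rows")
})

test_that("the permutation test honours its p-value conventions", {
  # no sub-alpha sample in the observed data: no clusters, p = 1 convention
  d0 <- reduced_null(27, n_participants = 6, trials_per_participant = 12)
  cp0 <- cluster_permutation_test(d0, "pupil", "ecc_code",
                                  n_permutations = 100, seed = 2)
  if (nrow(cp0$clusters) == 0) {
    expect_equal(glance(cp0)$min_p_cluster, 1)
  }
  # a cluster larger than every null maximum gets the add-one floor.
  # The boxcar effect must be strong enough that every within-window sample
  # is significant, yet weak enough that the null z's (whose residual
  # includes the permuted-out effect) stay nearly independent across
  # samples, keeping null clusters short
  set.seed(28)
  n <- 300; S <- 50
  code <- as.vector(replicate(10, sample(rep(c(-1, 1), 15))))
  Y <- matrix(rnorm(n * S), n, S)
  Y[, 11:40] <- Y[, 11:40] + 0.3 * code
  d <- trial_table(
    data.frame(participant = rep(sprintf("p%02d", 1:10), each = 30),
               ecc_code = code),
    list(pupil = Y), rate_hz = 100)
  cp <- cluster_permutation_test(d, "pupil", "ecc_code",
                                 n_permutations = 199, seed = 3)
  expect_true(any(cp$clusters$size >= 30))
  expect_gte(nrow(cp$clusters), 1)
  expect_equal(min(cp$clusters$p_cluster), 1 / 200)
  expect_true(all(cp$clusters$p_cluster >= 1 / 200))
  # character effects cannot be shuffled meaningfully
  d$ecc <- rep(c("a", "b"), length.out = nrow(d))
  expect_error(cluster_permutation_test(d, "pupil", "ecc"), "coding")
})

test_that("permutation results are reproducible under a fixed seed", {
  d <- reduced_null(29, n_participants = 6, trials_per_participant = 12)
  a <- cluster_permutation_test(d, "pupil", "ecc_code",
                                n_permutations = 100, seed = 7)
  b <- cluster_permutation_test(d, "pupil", "ecc_code",
                                n_permutations = 100, seed = 7)
  expect_identical(a$null_max, b$null_max)
  expect_identical(a$clusters, b$clusters)
  c2 <- cluster_permutation_test(d, "pupil", "ecc_code",
                                 n_permutations = 100, seed = 8)
  expect_false(identical(a$null_max, c2$null_max))
})

test_that("cross-validation localizes the effect and is deterministic", {
  sim <- simulate_dataset(reduced_spec(30, n_participants = 10,
                                       trials_per_participant = 21,
                                       effect_size = 50, slope_sd = 10,
                                       condition_values = c(near = -1,
                                                            medium = 0,
                                                            far = 1)))
  d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
  cv <- crossval_test(d, "pupil", "ecc_code")
  # all folds choose samples inside the true effect window [26, 50)
  expect_true(all(cv$chosen >= 26 & cv$chosen < 50))
  expect_lt(cv$results$p[1], 0.05)
  # bit-identical on rerun: the procedure has no randomness
  cv2 <- crossval_test(d, "pupil", "ecc_code")
  expect_identical(cv$results, cv2$results)
  expect_identical(cv$chosen, cv2$chosen)
  # tidy/glance accessors
  td <- tidy(cv)
  expect_true("tested_samples" %in% names(td))
  expect_equal(glance(cv)$n_folds, 4)
})

test_that("cross-validation power is non-decreasing in effect size", {
  rates <- vapply(c(0, 25, 50), function(es) {
    rej <- vapply(1:12, function(i) {
      sim <- simulate_dataset(reduced_spec(400 + i, n_participants = 8,
                                           trials_per_participant = 20,
                                           effect_size = es, slope_sd = 5))
      d <- pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
      cv <- crossval_test(d, "pupil", "ecc_code", random = "intercept")
      cv$results$p[1] < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("crossval refuses designs it cannot split", {
  d <- reduced_null(31, n_participants = 6, trials_per_participant = 12)
  expect_error(crossval_test(d, "pupil", "ecc_code", n_folds = 1),
               "at least 2")
  one <- d[d$participant == "p01", ]
  expect_error(crossval_test(one, "pupil", "ecc_code"), "participants")
})
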