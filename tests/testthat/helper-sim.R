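# Shared fixture builders. The reduced grid (500 ms at 1000 Hz, downsampled
# by 10 to 50 samples) is a faithful miniature of the full design: same
# pipeline, same per-sample noise structure, far cheaper per fit.

reduced_spec <- function(seed, n_participants = 10,
                         trials_per_participant = 20,
                         effect_size = 0, slope_sd = 0,
                         condition_values = c(a = -1, b = 1),
                         blink_rate = 0, ...) {
  synthetic_spec(
    n_participants = n_participants,
    trials_per_participant = trials_per_participant,
    rate_hz = 1000, epoch_ms = 500,
    condition_values = condition_values,
    effect_size = effect_size,
    effect_window = c(260, 500), kernel_tpeak_ms = 100,
    blink_rate = blink_rate, slope_sd = slope_sd, seed = seed, ...)
}

# simulate on the reduced grid and run the preprocessing the tests assume:
# downsample x10 (-> 50 samples) and subtractive baseline over the first
# 50 ms
reduced_null <- function(seed, ...) {
  sim <- simulate_dataset(reduced_spec(seed, ...))
  pp_baseline(pp_downsample(sim$data, 10), c(0, 50))
}

# tiny deterministic table for core-data tests
toy_table <- function() {
  trial_table(
    data.frame(participant = c("a", "a", "b", "b"), x = c(-1, 1, -1, 1)),
    series = list(pupil = matrix(as.numeric(1:20), nrow = 4)),
    rate_hz = 100
  )
}
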