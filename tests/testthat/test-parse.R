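# writer -> parser round trips use the <signal>_<phase> naming convention
as_phase_table <- function(data, phase = "cue") {
  scal <- data[setdiff(names(data), series_cols(data))]
  series <- list()
  for (s in series_cols(data)) {
    nm <- switch(s, pupil = paste0("pupil_", phase),
                 gaze_x = paste0("x_", phase), gaze_y = paste0("y_", phase))
    series[[nm]] <- data[[s]]
  }
  trial_table(scal, series, rate_hz = series_meta(data, "pupil")$rate_hz)
}

test_that("a written log parses back losslessly (values, vars, rate)", {
  sim <- simulate_dataset(reduced_spec(3, n_participants = 2,
                                       trials_per_participant = 4,
                                       blink_rate = 1))
  tt <- as_phase_table(sim$data)
  parsed <- parse_asc(write_asc(tt))
  expect_equal(nrow(parsed), nrow(tt))
  expect_equal(parsed$pupil_cue, tt$pupil_cue)
  expect_equal(parsed$x_cue, tt$x_cue)
  expect_equal(parsed$y_cue, tt$y_cue)
  expect_equal(as.character(parsed$ecc), tt$ecc)
  expect_equal(parsed$ecc_code, tt$ecc_code)   # numeric var stays numeric
  expect_equal(series_meta(parsed, "pupil_cue")$rate_hz, 1000)
})

test_that("round trip holds across random simulator draws", {
  for (seed in c(11, 12, 13)) {
    sim <- simulate_dataset(reduced_spec(seed, n_participants = 2,
                                         trials_per_participant = 3,
                                         blink_rate = 2))
    tt <- as_phase_table(sim$data)
    parsed <- parse_asc(write_asc(tt))
    expect_equal(parsed$pupil_cue, tt$pupil_cue)
  }
})

test_that("zero-coded pupil samples are recoded to missing on ingest", {
  lines <- c(
    "MSG 0 start_trial",
    "MSG 0 start_phase cue",
    "0 512 384 1800",
    "1 512 384 0",
    "2 512 384 1802",
    "MSG 3 end_phase cue",
    "MSG 3 var ecc far",
    "MSG 3 end_trial"
  )
  tt <- parse_asc(lines)
  expect_equal(as.vector(tt$pupil_cue), c(1800, NA, 1802))
  expect_equal(as.vector(tt$x_cue), c(512, NA, 512))
  expect_equal(tt$ecc, "far")
})

test_that("parser reports malformed input as specified", {
  expect_error(parse_asc(character()), "no trials")
  expect_error(parse_asc("MSG 0 recording"), "no trials")
  # unterminated trial is dropped with a warning
  lines_ok <- c("MSG 0 start_trial", "MSG 0 start_phase cue",
                "0 1 1 10", "1 1 1 11", "MSG 2 end_phase cue",
                "MSG 2 end_trial")
  expect_warning(parse_asc(c(lines_ok, "MSG 9 start_trial")),
                 "unterminated")
  # unparseable sample line skipped with a warning
  lines_bad <- append(lines_ok, "garbage line here", after = 3)
  expect_warning(tt <- parse_asc(lines_bad), "unparseable")
  expect_equal(ncol(tt$pupil_cue), 2)
  # non-monotonic timestamps are an error
  lines_mono <- c("MSG 0 start_trial", "MSG 0 start_phase cue",
                  "0 1 1 10", "5 1 1 11", "2 1 1 12",
                  "MSG 9 end_phase cue", "MSG 9 end_trial")
  expect_error(parse_asc(lines_mono), "monotonic")
})

test_that("dropped samples are filled to keep the time axis uniform", {
  lines <- c("MSG 0 start_trial", "MSG 0 start_phase cue",
             "0 1 1 10", "10 1 1 11", "40 1 1 14", "50 1 1 15",
             "MSG 60 end_phase cue", "MSG 60 end_trial")
  tt <- parse_asc(lines)
  expect_equal(series_meta(tt, "pupil_cue")$rate_hz, 100)
  expect_equal(as.vector(tt$pupil_cue), c(10, 11, NA, NA, 14, 15))
})

test_that("long-format tables pivot into trial tables", {
  lt <- data.frame(
    trial = rep(1:2, each = 3), participant = "s1", phase = "cue",
    t_ms = rep(c(0, 10, 20), 2),
    pupil = c(5, 6, 7, 8, 0, 9), x = 1, y = 2,
    rt = rep(c(300, 400), each = 3)
  )
  tt <- parse_long_table(lt)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$rt, c(300, 400))           # deduplicated per trial
  expect_equal(as.vector(tt$pupil_cue[2, ]), c(8, NA, 9))
  expect_equal(series_meta(tt, "pupil_cue")$rate_hz, 100)

  # interleaved participants are regrouped, chronological within
  lt2 <- lt
  lt2$participant <- rep(c("s2", "s1"), 3)
  lt2$trial <- 1
  lt2$rt <- 7
  out <- parse_long_table(lt2[order(lt2$t_ms), ])
  expect_equal(as.character(out$participant), c("s2", "s1"))

  expect_error(parse_long_table(lt[, setdiff(names(lt), "pupil")]),
               "pupil")
  lt3 <- lt
  lt3$rt[2] <- 999
  expect_error(parse_long_table(lt3), "inconsistent within trial 1")
})

test_that("an empty table writes a header-only stream", {
  tt <- toy_table()[0, ]
  expect_length(write_asc(tt), 1)
})
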