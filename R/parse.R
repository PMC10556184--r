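#' Message protocol of the ASCII eye-tracker dialect
#'
#' The parser reads a plain-text dialect inspired by EyeLink ASC exports.
#' Sample lines are `<timestamp> <x> <y> <pupil>` (whitespace-delimited,
#' timestamps in ms); everything else of interest is a message line
#' `MSG <timestamp> <payload>`. The payloads, configurable here, are:
#' `start_trial` / `end_trial`, `start_phase <name>` / `end_phase <name>`,
#' and `var <name> <value>` for per-trial experimental variables. A pupil
#' sample of 0 codes missing data and is recoded to `NA` on ingest.
#'
#' @param trial_start,trial_end Trial marker payloads.
#' @param phase_start,phase_end Phase marker prefixes (phase name follows).
#' @param var Variable message prefix.
#' @return A `message_protocol` list.
#' @export
message_protocol <- function(trial_start = "start_trial",
                             trial_end = "end_trial",
                             phase_start = "start_phase",
                             phase_end = "end_phase",
                             var = "var") {
  p <- as.list(environment())
  stopifnot(all(vapply(p, is.character, logical(1))),
            all(nchar(unlist(p)) > 0))
  class(p) <- "message_protocol"
  p
}

#' Parse an ASCII eye-tracker log into a trial table
#'
#' Splits the recording into trials and, within trials, into named phases;
#' each phase yields one series column per signal (`pupil_<phase>`,
#' `x_<phase>`, `y_<phase>`) and each `var` message one scalar column.
#' The sampling rate is inferred per phase as the modal inter-sample
#' interval (rounded to integer Hz); dropped samples (timestamp gaps) are
#' filled with missing values so the time axis stays uniform, and ragged
#' phases are right-padded with missing values to the longest trial (the
#' per-trial padding is recorded in the scalar column `<phase>_n_pad`).
#' Epoch time zero is the phase-start message. Pupil values of 0 are
#' recoded to missing. Variable values that look fully numeric become
#' numeric columns.
#'
#' @param file Path to the log file, or a character vector of lines.
#' @param protocol A [message_protocol()].
#' @param participant Participant id stored in the `participant` column;
#'   defaults to a `participant` var in the log, else `"unknown"`.
#' @return A [trial_table()]. Unterminated trials are dropped with a
#'   warning; unparseable sample lines are skipped with a warning;
#'   non-monotonic timestamps within a trial are an error.
#' @export
parse_asc <- function(file, protocol = message_protocol(),
                      participant = NULL) {
  lines <- if (length(file) == 1 && file.exists(file)) {
    readr::read_lines(file, progress = FALSE)
  } else {
    as.character(file)
  }
  trials <- list()
  cur <- NULL        # current trial accumulator
  phase <- NULL
  n_bad_samples <- 0L

  finish_phase <- function(cur) {
    if (!is.null(cur$phase) && length(cur$buf_t)) {
      cur$phases[[cur$phase]] <- list(
        t = cur$buf_t, x = cur$buf_x, y = cur$buf_y, p = cur$buf_p,
        t0 = cur$phase_t0)
    }
    cur$phase <- NULL
    cur$buf_t <- cur$buf_x <- cur$buf_y <- cur$buf_p <- numeric()
    cur
  }

  for (ln in lines) {
    if (startsWith(ln, "MSG")) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) < 3) next
      ts <- suppressWarnings(as.numeric(tok[2]))
      payload <- tok[-(1:2)]
      head1 <- payload[1]
      rest <- paste(payload, collapse = " ")
      if (rest == protocol$trial_start) {
        cur <- list(vars = list(), phases = list(), phase = NULL,
                    buf_t = numeric(), buf_x = numeric(),
                    buf_y = numeric(), buf_p = numeric())
      } else if (rest == protocol$trial_end) {
        if (!is.null(cur)) {
          cur <- finish_phase(cur)
          trials[[length(trials) + 1L]] <- cur
          cur <- NULL
        }
      } else if (!is.null(cur) && head1 == protocol$phase_start &&
                 length(payload) >= 2) {
        cur <- finish_phase(cur)
        cur$phase <- payload[2]
        cur$phase_t0 <- ts
      } else if (!is.null(cur) && head1 == protocol$phase_end) {
        cur <- finish_phase(cur)
      } else if (!is.null(cur) && head1 == protocol$var &&
                 length(payload) >= 3) {
        cur$vars[[payload[2]]] <- paste(payload[-(1:2)], collapse = " ")
      }
    } else if (!is.null(cur) && !is.null(cur$phase) && nzchar(trimws(ln))) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) < 4 || anyNA(vals[1])) {
        n_bad_samples <- n_bad_samples + 1L
        next
      }
      i <- length(cur$buf_t) + 1L
      if (i > 1 && vals[1] <= cur$buf_t[i - 1]) {
        stop("non-monotonic timestamps within a trial (at t = ", vals[1],
             ")", call. = FALSE)
      }
      cur$buf_t[i] <- vals[1]
      cur$buf_x[i] <- vals[2]
      cur$buf_y[i] <- vals[3]
      cur$buf_p[i] <- vals[4]
    }
  }
  if (!is.null(cur)) {
    warning("dropped 1 unterminated trial at end of stream", call. = FALSE)
  }
  if (n_bad_samples > 0) {
    warning("skipped ", n_bad_samples, " unparseable sample line(s)",
            call. = FALSE)
  }
  if (length(trials) == 0) stop("no trials found", call. = FALSE)

  phase_names <- unique(unlist(lapply(trials, function(tr) names(tr$phases))))
  var_names <- unique(unlist(lapply(trials, function(tr) names(tr$vars))))

  # scalar columns: numeric when every observed value parses as a number
  scalars <- tibble::tibble(.rows = length(trials))
  for (v in var_names) {
    vals <- vapply(trials, function(tr) {
      x <- tr$vars[[v]]
      if (is.null(x)) NA_character_ else x
    }, character(1))
    num <- suppressWarnings(as.numeric(vals))
    scalars[[v]] <- if (all(is.na(num) == is.na(vals))) num else vals
  }
  if (!"participant" %in% names(scalars)) {
    scalars$participant <- participant %||% "unknown"
  }

  series <- list()
  rates <- list()
  t0s <- list()
  for (ph in phase_names) {
    # modal inter-sample interval across all trials in this phase
    diffs <- unlist(lapply(trials, function(tr) {
      b <- tr$phases[[ph]]
      if (is.null(b) || length(b$t) < 2) numeric() else diff(b$t)
    }))
    dt <- if (length(diffs)) {
      as.numeric(names(sort(table(diffs), decreasing = TRUE))[1])
    } else {
      1
    }
    rate <- round(1000 / dt)
    dt <- 1000 / rate
    grids <- lapply(trials, function(tr) {
      b <- tr$phases[[ph]]
      if (is.null(b) || length(b$t) == 0) {
        return(list(x = numeric(), y = numeric(), p = numeric()))
      }
      idx <- as.integer(round((b$t - b$t[1]) / dt)) + 1L
      n <- max(idx)
      g <- list(x = rep(NA_real_, n), y = rep(NA_real_, n),
                p = rep(NA_real_, n))
      g$x[idx] <- b$x
      g$y[idx] <- b$y
      g$p[idx] <- b$p
      miss <- !is.na(g$p) & g$p == 0   # 0-coded missing pupil
      g$p[miss] <- NA_real_
      g$x[miss] <- NA_real_            # no gaze while the eyelid is closed
      g$y[miss] <- NA_real_
      g
    })
    n_max <- max(vapply(grids, function(g) length(g$p), integer(1)))
    pad <- function(v) c(v, rep(NA_real_, n_max - length(v)))
    for (sig in c("pupil", "x", "y")) {
      key <- switch(sig, pupil = "p", x = "x", y = "y")
      m <- do.call(rbind, lapply(grids, function(g) pad(g[[key]])))
      series[[paste0(sig, "_", ph)]] <- m
      rates[[paste0(sig, "_", ph)]] <- rate
      t0s[[paste0(sig, "_", ph)]] <- 0
    }
    scalars[[paste0(ph, "_n_pad")]] <-
      n_max - vapply(grids, function(g) length(g$p), integer(1))
  }
  trial_table(scalars, series, rate_hz = rates, t0_ms = t0s)
}

#' Write a trial table as an ASCII eye-tracker log
#'
#' Inverse of [parse_asc()] and the round-trip fixture writer: series
#' columns named `<signal>_<phase>` are grouped by phase and written as
#' sample lines between phase markers; other scalar columns become `var`
#' messages. Missing pupil samples are written as 0, the raw stream's
#' missing code, and are recovered as missing on re-parse.
#'
#' @param data A trial table whose series columns follow the
#'   `<signal>_<phase>` naming with signals `pupil`, `x`, `y`.
#' @param file Optional path; if `NULL` the lines are returned invisibly.
#' @param protocol A [message_protocol()].
#' @return Character vector of log lines, invisibly if written to `file`.
#' @export
write_asc <- function(data, file = NULL, protocol = message_protocol()) {
  sc <- series_cols(data)
  phases <- unique(sub("^(pupil|x|y)_", "", sc[grepl("^(pupil|x|y)_", sc)]))
  scalar_names <- setdiff(names(data), c(sc, grep("_n_pad$", names(data),
                                                  value = TRUE)))
  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  ts <- 0
  fmt <- function(x) formatC(x, format = "fg", digits = 15)
  for (i in seq_len(max(1, nrow(data)))) {
    if (nrow(data) == 0) break
    push("MSG ", fmt(ts), " ", protocol$trial_start)
    for (ph in phases) {
      pcol <- paste0("pupil_", ph)
      if (!pcol %in% sc) next
      meta <- series_meta(data, pcol)
      dt <- 1000 / meta$rate_hz
      push("MSG ", fmt(ts), " ", protocol$phase_start, " ", ph)
      p <- data[[pcol]][i, ]
      x <- if (paste0("x_", ph) %in% sc) data[[paste0("x_", ph)]][i, ] else
        rep(0, length(p))
      y <- if (paste0("y_", ph) %in% sc) data[[paste0("y_", ph)]][i, ] else
        rep(0, length(p))
      np <- length(p)
      tvec <- ts + (seq_len(np) - 1) * dt
      pw <- ifelse(is.na(p), 0, p)
      xw <- ifelse(is.na(x), 0, x)
      yw <- ifelse(is.na(y), 0, y)
      out <- c(out, paste(fmt(tvec), fmt(xw), fmt(yw), fmt(pw)))
      ts <- ts + np * dt
      push("MSG ", fmt(ts), " ", protocol$phase_end, " ", ph)
      ts <- ts + dt
    }
    for (v in scalar_names) {
      push("MSG ", fmt(ts), " ", protocol$var, " ", v, " ", data[[v]][i])
    }
    push("MSG ", fmt(ts), " ", protocol$trial_end)
    ts <- ts + 100
  }
  if (nrow(data) == 0) out <- paste0("MSG 0 recording")
  if (!is.null(file)) {
    readr::write_lines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse a long-format samples table into a trial table
#'
#' Accepts the common one-row-per-sample spreadsheet layout with columns
#' `trial`, `participant`, `phase`, `t_ms`, `pupil`, `x`, `y`; any further
#' columns are treated as per-trial scalars and must be constant within a
#' trial. Rows are grouped by participant (order of first appearance) and
#' kept chronological within participant. Pupil values of 0 are recoded to
#' missing.
#'
#' @param x A data frame, or a path to a delimited text file readable by
#'   [readr::read_delim()] (delimiter guessed).
#' @return A [trial_table()] with series columns `pupil_<phase>`,
#'   `x_<phase>`, `y_<phase>`.
#' @export
parse_long_table <- function(x) {
  d <- if (is.character(x) && length(x) == 1) {
    readr::read_delim(x, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  req <- c("trial", "participant", "phase", "t_ms", "pupil", "x", "y")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("long table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(d), req)
  d$participant <- as.character(d$participant)

  # chronological within participant, participants in order of appearance
  d <- d[order(match(d$participant, unique(d$participant)),
               d$trial, d$t_ms), ]
  keys <- unique(d[, c("participant", "trial")])

  scalars <- tibble::tibble(participant = keys$participant,
                            trial = keys$trial)
  for (v in extra) {
    vals <- vector("list", nrow(keys))
    for (j in seq_len(nrow(keys))) {
      i <- d$participant == keys$participant[j] & d$trial == keys$trial[j]
      u <- unique(d[[v]][i])
      u <- u[!is.na(u)]
      if (length(u) > 1) {
        stop("scalar column `", v, "` is inconsistent within trial ",
             keys$trial[j], " of participant ", keys$participant[j],
             call. = FALSE)
      }
      vals[[j]] <- if (length(u)) u else NA
    }
    scalars[[v]] <- unlist(vals)
  }

  series <- list()
  rates <- list()
  for (ph in unique(d$phase)) {
    dp <- d[d$phase == ph, ]
    dt_all <- unlist(tapply(dp$t_ms,
                            paste(dp$participant, dp$trial), diff))
    dt <- if (length(dt_all)) {
      as.numeric(names(sort(table(dt_all), decreasing = TRUE))[1])
    } else {
      1
    }
    rate <- round(1000 / dt)
    mats <- lapply(c("pupil", "x", "y"), function(sig) {
      rows <- lapply(seq_len(nrow(keys)), function(j) {
        i <- dp$participant == keys$participant[j] &
          dp$trial == keys$trial[j]
        v <- dp[[sig]][i]
        if (sig == "pupil") v[v == 0] <- NA_real_
        v
      })
      n_max <- max(1L, max(vapply(rows, length, integer(1))))
      do.call(rbind, lapply(rows, function(v) {
        c(v, rep(NA_real_, n_max - length(v)))
      }))
    })
    names(mats) <- paste0(c("pupil", "x", "y"), "_", ph)
    for (nmx in names(mats)) {
      series[[nmx]] <- mats[[nmx]]
      rates[[nmx]] <- rate
    }
  }
  t0s <- lapply(rates, function(...) 0)
  trial_table(scalars, series, rate_hz = rates, t0_ms = t0s)
}
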