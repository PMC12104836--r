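# Synthetic exam timelines: wake/sleep intervals, seizures, recording files.

SEIZURE_TYPES <- c("focal", "subclin", "sg")

#' Construct an exam timeline
#'
#' Holds the annotation layer of one icEEG exam: half-open wake/sleep state
#' intervals (seconds from exam start), seizure events, the spans covered by
#' recording files (with per-file sampling rate), the implant time and the
#' exam start datetime.
#'
#' @param states data.frame start/end/state (`W`,`N1`,`N2`,`N3`,`R`,`NA`).
#' @param seizures data.frame onset/duration/type (+ optional
#'   `onset_channels` list column).
#' @param files data.frame start/end/fs (+ optional `path`).
#' @param start_datetime POSIXct exam start.
#' @param implant_time seconds from exam start at which electrodes were
#'   implanted (default 0).
#' @param subject_id,hospital identity metadata.
#' @return object of class `exam_timeline`.
#' @export
exam_timeline <- function(states, seizures = NULL, files = NULL,
                          start_datetime = parse_datetime("2024-03-04T08:00:00"),
                          implant_time = 0, subject_id = "SYNH_001",
                          hospital = "SYNH") {
  states <- as.data.frame(states)
  assert_that(all(c("start", "end", "state") %in% names(states)),
              "states needs start/end/state")
  assert_that(all(states$end > states$start), "state intervals must be non-empty")
  if (nrow(states) > 1) {
    o <- order(states$start)
    states <- states[o, , drop = FALSE]
    assert_that(all(states$start[-1] >= states$end[-nrow(states)]),
                "state intervals must not overlap")
  }
  rownames(states) <- NULL
  if (is.null(seizures))
    seizures <- data.frame(onset = numeric(), duration = numeric(),
                           type = character(), stringsAsFactors = FALSE)
  assert_that(all(seizures$duration >= 0), "seizure durations must be >= 0")
  if (is.null(files))
    files <- data.frame(start = numeric(), end = numeric(), fs = numeric(),
                        path = character(), stringsAsFactors = FALSE)
  structure(list(states = states, seizures = seizures, files = files,
                 start_datetime = start_datetime, implant_time = implant_time,
                 subject_id = subject_id, hospital = hospital),
            class = "exam_timeline")
}

#' @export
print.exam_timeline <- function(x, ...) {
  cat(sprintf("<exam_timeline> %s: %.1f h, %d state intervals, %d seizures, %d files\n",
              x$subject_id, max(x$states$end) / 3600, nrow(x$states),
              nrow(x$seizures), nrow(x$files)))
  invisible(x)
}

exam_span <- function(timeline) max(timeline$states$end)

#' Generate a synthetic exam timeline
#'
#' Circadian wake/sleep alternation (sleep 23:00-07:00 cycling through
#' N1/N2/N3/REM blocks, daytime wake with occasional naps), seizures drawn
#' from a Poisson process at `config$seizure_rate` events/day with types from
#' the configured mix, and a fixed daily schedule of recording files (four
#' chunks/day at 09:00, 12:30, 16:00 and 19:30, `recording_chunk_s` seconds
#' each).
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index (seeds the subject's stream).
#' @return an [exam_timeline()].
#' @export
generate_timeline <- function(config, subject_index = 1L) {
  dur_s <- config$exam_duration * 3600
  start_dt <- parse_datetime("2024-03-04T08:00:00")
  start_hour <- 8
  with_seed(derive_seed(config$seed, "timeline", subject_index), {
    ## state intervals
    t <- 0
    starts <- numeric(); ends <- numeric(); st <- character()
    while (t < dur_s) {
      clock <- (start_hour + t / 3600) %% 24
      night <- clock >= 23 || clock < 7
      if (night) {
        state <- sample(c("N1", "N2", "N3", "R"), 1L,
                        prob = c(0.1, 0.4, 0.3, 0.2))
        block <- stats::runif(1, 20, 45) * 60
        # do not run a sleep block past 07:00
        till_morning <- ((7 - clock) %% 24) * 3600
        block <- min(block, till_morning)
      } else if (stats::runif(1) < 0.08 && clock >= 13 && clock < 16) {
        state <- "N2" # afternoon nap
        block <- stats::runif(1, 30, 60) * 60
      } else {
        state <- "W"
        block <- stats::runif(1, 0.5, 2.5) * 3600
        till_night <- ((23 - clock) %% 24) * 3600
        block <- min(block, till_night)
      }
      block <- min(block, dur_s - t)
      starts <- c(starts, t); ends <- c(ends, t + block); st <- c(st, state)
      t <- t + block
    }
    # round boundaries to ms (sub-ms slivers from boundary truncation do
    # not survive serialisation), drop empties, repair contiguity, merge runs
    starts <- round(starts, 3); ends <- round(ends, 3)
    ok <- ends > starts
    starts <- starts[ok]; ends <- ends[ok]; st <- st[ok]
    starts <- c(0, ends[-length(ends)])
    ends[length(ends)] <- round(dur_s, 3)
    keep <- c(TRUE, st[-1] != st[-length(st)])
    grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
    states <- data.frame(
      start = as.numeric(tapply(starts, grp, min)),
      end = as.numeric(tapply(ends, grp, max)),
      state = st[keep], stringsAsFactors = FALSE, row.names = NULL)

    ## seizures: Poisson process
    n_sz <- stats::rpois(1L, config$seizure_rate * config$exam_duration / 24)
    if (n_sz > 0) {
      onset <- sort(stats::runif(n_sz, 0, dur_s))
      type <- sample(names(config$seizure_type_mix), n_sz, replace = TRUE,
                     prob = config$seizure_type_mix)
      meanlog <- c(focal = log(90), subclin = log(30), sg = log(120))[type]
      sdlog <- c(focal = 0.4, subclin = 0.4, sg = 0.3)[type]
      duration <- stats::rlnorm(n_sz, meanlog, sdlog)
      all_names <- generate_geometry(config, seed = config$seed)$channels$name
      onset_channels <- lapply(seq_len(n_sz), function(i)
        sample(all_names, sample(1:3, 1L)))
      seizures <- data.frame(onset = onset, duration = duration, type = type,
                             stringsAsFactors = FALSE, row.names = NULL)
      seizures$onset_channels <- onset_channels
    } else {
      seizures <- data.frame(onset = numeric(), duration = numeric(),
                             type = character(), stringsAsFactors = FALSE)
    }

    ## recording file schedule: 09:00, 12:30, 16:00, 19:30 daily
    chunk_clock <- c(9, 12.5, 16, 19.5)
    n_days <- ceiling(config$exam_duration / 24)
    chunk_starts <- as.vector(outer((chunk_clock - start_hour) * 3600,
                                    (seq_len(n_days) - 1) * 86400, `+`))
    chunk_starts <- sort(chunk_starts[chunk_starts >= 0 &
                                      chunk_starts + config$recording_chunk_s <= dur_s])
    files <- data.frame(
      start = chunk_starts,
      end = chunk_starts + config$recording_chunk_s,
      fs = config$sampling_rate,
      path = sprintf("chunk_%03d", seq_along(chunk_starts)),
      stringsAsFactors = FALSE)

    exam_timeline(states, seizures, files, start_datetime = start_dt,
                  implant_time = 0,
                  subject_id = subject_ids(config)[subject_index],
                  hospital = config$hospital)
  })
}

#' Write / read an exam timeline as JSON
#'
#' @param timeline an [exam_timeline()].
#' @param path JSON file path.
#' @return `path` / the timeline.
#' @export
write_timeline <- function(timeline, path) {
  x <- list(
    format = "normkit-timeline-v1",
    subject_id = timeline$subject_id,
    hospital = timeline$hospital,
    start_datetime = format_datetime(timeline$start_datetime),
    implant_time = timeline$implant_time,
    states = timeline$states,
    seizures = timeline$seizures,
    files = timeline$files
  )
  write_json_file(x, path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  x <- read_json_file(path)
  assert_that(identical(x$format, "normkit-timeline-v1"), "not a timeline file")
  sz <- as.data.frame(x$seizures)
  fl <- as.data.frame(x$files)
  if (!nrow(sz)) sz <- NULL
  if (!nrow(fl)) fl <- NULL
  exam_timeline(as.data.frame(x$states), sz, fl,
                start_datetime = parse_datetime(x$start_datetime),
                implant_time = x$implant_time,
                subject_id = x$subject_id, hospital = x$hospital)
}
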