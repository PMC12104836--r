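# Temporal processing: interictal segment selection under the
# decision-point constraints, extraction, and channel quality flags.

#' Construct a segment selection policy
#'
#' Bundles the temporal decision points: required state of consciousness,
#' per-seizure-type exclusion buffers, minimum sampling frequency, segment
#' length, number of segments, minimum start-to-start separation, the
#' post-implantation skip and an optional clock-time window.
#'
#' @param state required wake status (default `"W"`, relaxed wakefulness).
#' @param seizure_buffer hours kept clear either side of every seizure;
#'   either a single number or a named vector over focal/subclin/sg
#'   (default 2 h for all types).
#' @param min_fs minimum acceptable sampling frequency, Hz (default 200).
#' @param segment_length segment duration in seconds (default 70).
#' @param n_segments segments requested per subject (default 3, taken
#'   "where possible").
#' @param min_separation minimum start-to-start separation between selected
#'   segments, hours (default 4).
#' @param post_implant_skip hours discarded after implantation (default 24).
#' @param time_of_day_window optional `c(start_hour, end_hour)` clock window
#'   (e.g. `c(8, 22)` to restrict wake selection to 8 am-10 pm).
#' @return object of class `selection_policy`.
#' @export
selection_policy <- function(state = "W",
                             seizure_buffer = 2,
                             min_fs = 200,
                             segment_length = 70,
                             n_segments = 3,
                             min_separation = 4,
                             post_implant_skip = 24,
                             time_of_day_window = NULL) {
  if (length(seizure_buffer) == 1L && is.null(names(seizure_buffer)))
    seizure_buffer <- stats::setNames(rep(seizure_buffer, 3), SEIZURE_TYPES)
  assert_that(all(names(seizure_buffer) %in% SEIZURE_TYPES),
              "seizure_buffer names must be focal/subclin/sg")
  assert_that(all(seizure_buffer > 0) && segment_length > 0 &&
                min_separation > 0 && min_fs > 0,
              "all durations and rates must be positive")
  assert_that(n_segments >= 1, "n_segments must be >= 1")
  assert_that(state %in% c("W", "N1", "N2", "N3", "R"), "invalid state")
  structure(list(state = state, seizure_buffer = seizure_buffer,
                 min_fs = min_fs, segment_length = segment_length,
                 n_segments = as.integer(n_segments),
                 min_separation = min_separation,
                 post_implant_skip = post_implant_skip,
                 time_of_day_window = time_of_day_window),
            class = "selection_policy")
}

#' Periods in the required state of consciousness
#'
#' Intersects the timeline's state intervals with the policy's state, the
#' optional clock-time window, and the post-implantation skip.
#'
#' @param timeline an [exam_timeline()].
#' @param policy a [selection_policy()].
#' @return data.frame of half-open intervals (start/end seconds).
#' @export
state_periods <- function(timeline, policy) {
  st <- timeline$states
  iv <- intervals(st$start[st$state == policy$state],
                  st$end[st$state == policy$state])
  skip_until <- timeline$implant_time + policy$post_implant_skip * 3600
  iv <- interval_intersect(iv, intervals(skip_until, Inf))
  if (!is.null(policy$time_of_day_window)) {
    w <- policy$time_of_day_window
    start_clock <- as.numeric(format(timeline$start_datetime, "%H")) +
      as.numeric(format(timeline$start_datetime, "%M")) / 60
    span <- exam_span(timeline)
    # daily windows in exam seconds
    day0 <- -start_clock * 3600
    days <- seq(day0, span, by = 86400)
    win <- intervals(days + w[1] * 3600, days + w[2] * 3600)
    iv <- interval_intersect(iv, win)
  }
  iv
}

#' Remove seizure exclusion buffers from candidate intervals
#'
#' Subtracts `[onset - buffer(type), onset + duration + buffer(type))` for
#' every seizure. Idempotent; total duration never increases.
#'
#' @param iv data.frame of half-open intervals.
#' @param seizures data.frame onset/duration/type.
#' @param buffer named hours per seizure type (as in [selection_policy()]).
#' @return interval data.frame.
#' @export
remove_seizure_buffer <- function(iv, seizures, buffer) {
  if (is.null(seizures) || !nrow(seizures)) return(iv)
  unknown <- setdiff(unique(seizures$type), names(buffer))
  if (length(unknown))
    abort_normkit(sprintf("no buffer defined for seizure type(s): %s",
                          paste(unknown, collapse = ", ")),
                  "normkit_unknown_seizure_type")
  b <- buffer[seizures$type] * 3600
  cut <- intervals(seizures$onset - b, seizures$onset + seizures$duration + b)
  interval_subtract(iv, cut)
}

# Steps A3-A4: drop candidate intervals below the fs floor or shorter than
# one segment. Intervals must carry an `fs` column (from the file schedule).
filter_fs_and_length <- function(iv, policy) {
  assert_that("fs" %in% names(iv), "intervals must carry an fs column")
  iv[iv$fs >= policy$min_fs &
       (iv$end - iv$start) >= policy$segment_length, , drop = FALSE]
}

#' Greedy placement of fixed-length segments
#'
#' Earliest-first placement of up to `n_segments` starts, each fully inside
#' one candidate interval and separated start-to-start by at least
#' `min_separation` hours. Returns fewer placements when the interval set
#' cannot support the request ("where possible"); never errors for
#' shortfall.
#'
#' @param iv candidate intervals (post-buffer, post-filter).
#' @param policy a [selection_policy()].
#' @return numeric vector of segment start times (seconds).
#' @export
select_segments <- function(iv, policy) {
  sep <- policy$min_separation * 3600
  len <- policy$segment_length
  starts <- numeric()
  if (!nrow(iv)) return(starts)
  iv <- iv[order(iv$start), , drop = FALSE]
  cursor <- -Inf
  for (i in seq_len(nrow(iv))) {
    s <- max(iv$start[i], cursor)
    while (length(starts) < policy$n_segments && s + len <= iv$end[i]) {
      starts <- c(starts, s)
      cursor <- s + sep
      s <- max(s + sep, iv$start[i])
    }
    if (length(starts) >= policy$n_segments) break
  }
  starts
}

#' Extract a segment from a cohort recording
#'
#' Slices `[start, start + segment_length)` out of the recording file
#' covering the placement and populates the full extraction metadata
#' (channel names, flags, datetime, duration, fs, wake status, identity,
#' segment number).
#'
#' @param recording_dir directory holding the subject's recording chunks.
#' @param timeline the subject's [exam_timeline()].
#' @param start placement start in seconds from exam start.
#' @param policy a [selection_policy()].
#' @param channel_names channel names for the recording rows.
#' @param segment_number 1-based index in selection order.
#' @param unsuitable_channels,spiking_channels flags to record.
#' @return a [segment_record()].
#' @export
extract_segment <- function(recording_dir, timeline, start, policy,
                            channel_names, segment_number = 1L,
                            unsuitable_channels = character(),
                            spiking_channels = character()) {
  len <- policy$segment_length
  f <- timeline$files
  hit <- which(f$start <= start & f$end >= start + len)
  if (!length(hit))
    abort_normkit(sprintf("placement [%g, %g) not covered by any recording file",
                          start, start + len), "normkit_bounds")
  f <- f[hit[1L], ]
  chunk <- read_recording_chunk(file.path(recording_dir, f$path))
  i0 <- round((start - f$start) * chunk$fs)
  n <- round(len * chunk$fs)
  assert_that(i0 >= 0 && i0 + n <= ncol(chunk$data), "placement outside chunk")
  data <- chunk$data[, (i0 + 1):(i0 + n), drop = FALSE]
  st <- timeline$states
  state <- st$state[st$start <= start & st$end > start]
  segment_record(
    data = data, channel_names = channel_names, fs = chunk$fs,
    start_datetime = timeline$start_datetime + start,
    duration = len,
    wake_status = if (length(state)) state[1L] else "NA",
    subject_id = timeline$subject_id, hospital = timeline$hospital,
    segment_number = segment_number,
    unsuitable_channels = unsuitable_channels,
    spiking_channels = spiking_channels)
}

#' Flag unsuitable channels in a segment
#'
#' Automated stand-in for visual channel QC: flags channels that are
#' flatlined (zero variance), whose log total power is a robust-z outlier
#' across channels, or whose log-log PSD slope over `slope_range` is
#' non-negative (non-1/f).
#'
#' @param segment a [segment_record()].
#' @param z_max robust-z threshold on log10 total power (default 3).
#' @param slope_max maximum acceptable log-log PSD slope (default 0:
#'   physiological spectra fall with frequency).
#' @param slope_range frequency range (Hz) for the slope fit.
#' @return character vector of flagged channel names.
#' @export
flag_unsuitable_channels <- function(segment, z_max = 3, slope_max = 0,
                                     slope_range = c(2, 45)) {
  assert_that(nrow(segment$data) >= 2,
              "need at least two channels for cross-channel reference")
  w <- welch_psd(segment$data, segment$fs)
  total <- rowSums(w$psd)
  vars <- apply(segment$data, 1L, stats::var)
  flat <- vars == 0
  z <- rep(0, length(total))
  pos <- total > 0
  z[pos] <- robust_z(log10(total[pos]))
  sel <- w$freq >= slope_range[1] & w$freq <= slope_range[2]
  lf <- log10(w$freq[sel])
  slope <- apply(w$psd[, sel, drop = FALSE], 1L, function(p) {
    if (any(p <= 0)) return(Inf)
    stats::coef(stats::lm.fit(cbind(1, lf), log10(p)))[2]
  })
  flagged <- flat | abs(z) > z_max | slope >= slope_max
  segment$channel_names[flagged]
}

#' Run the full temporal selection for one subject
#'
#' State periods -> recording-file intersection -> seizure buffers -> fs and
#' length filters -> greedy placement -> extraction with channel QC flags.
#'
#' @param recording_dir the subject's `raw-eeg` directory.
#' @param timeline the subject's [exam_timeline()].
#' @param policy a [selection_policy()].
#' @param channel_names recording channel names.
#' @param known_spiking channels already flagged as spiking (annotations).
#' @return list of [segment_record()]s (possibly empty), with the placement
#'   trace in `attr(, "trace")`.
#' @export
plan_and_extract_segments <- function(recording_dir, timeline, policy,
                                      channel_names,
                                      known_spiking = character()) {
  iv <- state_periods(timeline, policy)
  iv_rec <- interval_intersect(
    intervals(timeline$files$start, timeline$files$end, fs = timeline$files$fs),
    iv)
  iv_buf <- remove_seizure_buffer(iv_rec, timeline$seizures,
                                  policy$seizure_buffer)
  iv_ok <- filter_fs_and_length(iv_buf, policy)
  starts <- select_segments(iv_ok, policy)
  segs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    seg <- extract_segment(recording_dir, timeline, starts[k], policy,
                           channel_names, segment_number = k,
                           spiking_channels = intersect(known_spiking,
                                                        channel_names))
    if (nrow(seg$data) >= 2)
      seg$unsuitable_channels <- flag_unsuitable_channels(seg)
    segs[[k]] <- seg
  }
  attr(segs, "trace") <- list(
    state_s = interval_total(iv), recorded_s = interval_total(iv_rec),
    post_buffer_s = interval_total(iv_buf), eligible_s = interval_total(iv_ok),
    placements = starts)
  segs
}
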