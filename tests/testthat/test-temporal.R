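all_wake <- function(hours = 48, fs = 256) {
  exam_timeline(data.frame(start = 0, end = hours * 3600, state = "W"),
                files = data.frame(start = 0, end = hours * 3600, fs = fs,
                                   path = "chunk_001"))
}

test_that("state periods honour state, skip window and clock window", {
  pol <- default_policy()
  iv <- state_periods(all_wake(48), pol)
  expect_equal(iv$start, 24 * 3600)
  expect_equal(iv$end, 48 * 3600)

  expect_equal(nrow(state_periods(all_wake(48), selection_policy(state = "N3"))), 0)

  # clock window: exam starts 08:00, so 8am-10pm day 2 is [24 h, 38 h)
  pol_win <- selection_policy(time_of_day_window = c(8, 22))
  ivw <- state_periods(all_wake(48), pol_win)
  expect_equal(ivw$start, 24 * 3600)
  expect_equal(ivw$end, 38 * 3600)
})

test_that("seizure buffers subtract per type and idempotently", {
  iv <- normkit:::intervals(0, 10 * 3600, fs = 256)
  sz <- data.frame(onset = 5 * 3600, duration = 60, type = "focal")
  buf <- c(focal = 2, subclin = 2, sg = 2)
  out <- remove_seizure_buffer(iv, sz, buf)
  expect_equal(out$start, c(0, 7 * 3600 + 60))
  expect_equal(out$end, c(3 * 3600, 10 * 3600))
  expect_identical(remove_seizure_buffer(out, sz, buf), out) # idempotent

  # no seizures: identity
  expect_identical(remove_seizure_buffer(iv, NULL, buf), iv)

  # per-type buffers: stricter focal window
  buf2 <- c(focal = 4, subclin = 1, sg = 2)
  sz2 <- data.frame(onset = c(5, 20) * 3600, duration = c(60, 30),
                    type = c("focal", "subclin"))
  out2 <- remove_seizure_buffer(normkit:::intervals(0, 24 * 3600), sz2, buf2)
  expect_equal(out2$start[1], 0)
  expect_equal(out2$end[1], 1 * 3600)
  expect_equal(out2$start[2], 9 * 3600 + 60)

  # buffer swallowing the whole exam
  expect_equal(nrow(remove_seizure_buffer(
    normkit:::intervals(0, 3600), data.frame(onset = 1800, duration = 10,
                                             type = "sg"), buf)), 0)

  # unknown type is an error naming the type
  expect_error(remove_seizure_buffer(iv, data.frame(onset = 10, duration = 1,
                                                    type = "atonic"), buf),
               "atonic")
})

test_that("greedy placement matches the hand trace and constraints", {
  pol <- default_policy()
  iv <- normkit:::intervals(0, 10 * 3600, fs = 256)
  expect_equal(select_segments(iv, pol), c(0, 4, 8) * 3600)

  # infeasible request degrades gracefully
  expect_length(select_segments(normkit:::intervals(0, 3 * 3600, fs = 256), pol), 1)
  expect_length(select_segments(iv[0, ], pol), 0)

  # property: random interval sets always satisfy separation + containment
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    s <- sort(runif(n, 0, 40) * 3600)
    iv <- normkit:::intervals(s, s + runif(n, 0.01, 6) * 3600, fs = 256)
    iv <- normkit:::interval_union(iv); iv$fs <- 256
    st <- select_segments(iv, pol)
    if (length(st) > 1)
      expect_true(all(diff(st) >= pol$min_separation * 3600))
    for (x in st)
      expect_true(any(iv$start <= x & iv$end >= x + pol$segment_length))
    expect_lte(length(st), pol$n_segments)
  }
})

test_that("extraction slices the right samples with full metadata", {
  dir <- tempfile("rec"); dir.create(dir)
  fs <- 256
  data <- matrix(seq_len(3 * 200 * fs) / 1000, nrow = 3)
  normkit:::write_recording_chunk(data, fs, start = 90000,
                                  file.path(dir, "chunk_001"))
  tl <- exam_timeline(data.frame(start = 0, end = 48 * 3600, state = "W"),
                      files = data.frame(start = 90000, end = 90200, fs = fs,
                                         path = "chunk_001"))
  pol <- default_policy()
  seg <- extract_segment(dir, tl, 90010, pol, c("A1", "A2", "A3"),
                         segment_number = 2L)
  expect_equal(ncol(seg$data), 70 * fs) # 17,920 columns
  expect_equal(seg$segment_number, 2L)
  expect_equal(seg$wake_status, "W")
  expect_equal(normkit:::format_datetime(seg$start_datetime),
               normkit:::format_datetime(tl$start_datetime + 90010))
  # float32 chunk quantisation: values match to single precision
  expect_equal(unname(seg$data[, 1]), data[, 10 * fs + 1], tolerance = 1e-6)

  expect_error(extract_segment(dir, tl, 90150, pol, c("A1", "A2", "A3")),
               "not covered")
  unlink(dir, recursive = TRUE)
})

test_that("segment containers round-trip bit-exactly", {
  seg <- make_segment(matrix(rnorm(4 * 1000), nrow = 4), fs = 200,
                      unsuitable_channels = "ch2", spiking_channels = "ch3",
                      wake_status = "N2", segment_number = 3L)
  stem <- tempfile("seg")
  write_segment(seg, stem)
  back <- read_segment(stem)
  expect_identical(back$data, seg$data)
  expect_identical(back$unsuitable_channels, "ch2")
  expect_identical(back$spiking_channels, "ch3")
  expect_identical(back$segment_number, 3L)
  expect_identical(back$wake_status, "N2")
  expect_equal(back$fs, seg$fs)
  unlink(paste0(stem, c(".dat", ".json")))
})

test_that("unsuitable-channel flags follow the documented rules", {
  fs <- 200
  # identical-statistics physiological (1/f) channels, one with 100x variance
  prof <- matrix(rep(c(0.3, 0.3, 0.15, 0.15, 0.1), each = 11), nrow = 11)
  base <- generate_signal(prof, 10, fs, line_noise_hz = 0, seed = 7)
  base[11, ] <- base[11, ] * 10
  seg <- make_segment(base, fs = fs)
  expect_identical(flag_unsuitable_channels(seg), "ch11")

  # all-identical channels: none flagged
  same <- base[rep(1, 5), , drop = FALSE]
  expect_length(flag_unsuitable_channels(make_segment(same, fs = fs)), 0)

  # flatline is always flagged
  flat <- base; flat[4, ] <- 2.5
  expect_true("ch4" %in% flag_unsuitable_channels(make_segment(flat, fs = fs)))

  # white noise is non-1/f: caught by the spectral-slope rule
  wn <- base; set.seed(8); wn[6, ] <- rnorm(ncol(base)) * sd(base[6, ])
  expect_true("ch6" %in% flag_unsuitable_channels(make_segment(wn, fs = fs)))

  expect_error(flag_unsuitable_channels(
    make_segment(matrix(rnorm(10 * fs), nrow = 1), fs = fs)), "two channels")
})
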