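cc_small <- cohort_config(n_subjects = 2, exam_duration = 48, seed = 7)

test_that("timelines are deterministic under config + seed", {
  t1 <- generate_timeline(cc_small, 1)
  t2 <- generate_timeline(cc_small, 1)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$seizures, t2$seizures)
  expect_identical(t1$files, t2$files)
  t3 <- generate_timeline(cc_small, 2)
  expect_false(identical(t1$states, t3$states))
})

test_that("timeline structure respects the exam span and alternation", {
  tl <- generate_timeline(cc_small, 1)
  st <- tl$states
  expect_equal(st$start[1], 0)
  expect_equal(st$end[nrow(st)], 48 * 3600)
  expect_true(all(st$start[-1] == st$end[-nrow(st)])) # contiguous
  expect_true(all(st$state[-1] != st$state[-nrow(st)])) # merged runs
  expect_true(all(tl$seizures$onset >= 0 &
                    tl$seizures$onset <= 48 * 3600))
})

test_that("zero seizure rate gives an empty event list", {
  cc0 <- cohort_config(n_subjects = 1, exam_duration = 24, seizure_rate = 0,
                       seed = 3)
  expect_equal(nrow(generate_timeline(cc0, 1)$seizures), 0)
})

test_that("seizure counts follow the Poisson closed form", {
  cc <- cohort_config(n_subjects = 1, exam_duration = 120, seizure_rate = 2,
                      seed = 1)
  counts <- vapply(1:200, function(s) {
    cci <- cc; cci$seed <- s
    nrow(generate_timeline(cci, 1)$seizures)
  }, numeric(1))
  lambda <- 2 * 5 # 2/day over 5 days
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("signal generator realises the requested spectral structure", {
  # all oscillatory power in alpha: PSD argmax inside [8, 13)
  prof <- matrix(c(0, 0, 1, 0, 0), nrow = 1)
  sig <- generate_signal(prof, 70, 200, line_noise_hz = 0, seed = 5,
                         oscillation_fraction = 0.95, line_fraction = 0)
  w <- welch_psd(sig, 200)
  fpeak <- w$freq[which.max(w$psd[1, ])]
  expect_gte(fpeak, 8); expect_lt(fpeak, 13)

  # background only: negative log-log slope
  bg <- generate_signal(matrix(rep(0.2, 5), 1), 70, 200, line_noise_hz = 0,
                        seed = 5, oscillation_fraction = 0, line_fraction = 0)
  wb <- welch_psd(bg, 200)
  sel <- wb$freq >= 2 & wb$freq <= 45
  fit <- coef(lm(log10(wb$psd[1, sel]) ~ log10(wb$freq[sel])))
  expect_lt(fit[2], 0)

  # determinism: bit-identical arrays
  s1 <- generate_signal(prof, 10, 200, seed = 11)
  s2 <- generate_signal(prof, 10, 200, seed = 11)
  expect_identical(s1, s2)
  # unrepresentable mains peak rejected
  expect_error(generate_signal(prof, 10, 100, line_noise_hz = 60, seed = 1),
               "mains")
})

test_that("band-power ranking is recovered in at least 95% of draws", {
  prof <- matrix(c(0.35, 0.25, 0.2, 0.12, 0.08), nrow = 1)
  hits <- vapply(1:100, function(s) {
    sig <- generate_signal(prof, 70, 200, line_noise_hz = 60, seed = s)
    rbp <- band_log_rbp(sig, fs = 200)
    identical(order(-rbp$rbp), order(-prof[1, ]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("geometry places channels on their true parcels", {
  g <- generate_geometry(cc_small, seed = 9)
  expect_equal(nrow(g$channels), cc_small$n_channels)
  expect_null(g$mask)
  for (i in seq_len(nrow(g$channels))) {
    o <- oracle_nearest_grey(as.numeric(g$channels[i, c("x", "y", "z")]),
                             g$parc, g$channels$hemisphere[i])
    expect_identical(o$roi_id, g$channels$true_roi[i])
  }
  gm <- generate_geometry(cc_small, seed = 9, resected_rois = 17L)
  expect_identical(sort(unique(g$parc$labels[gm$mask == 1L])), 17L)
})

test_that("cohorts write the expected layout and are reproducible", {
  cc <- cohort_config(n_subjects = 2, n_test_subjects = 1,
                      exam_duration = 24, pathological_rois = 17L,
                      pathology_shift_sd = 3, seed = 21)
  d1 <- tempfile("cohort")
  gt <- generate_cohort(cc, d1, write_recordings = FALSE)
  expect_true(all(dir.exists(file.path(d1, c("SYNH_001", "SYNH_002",
                                             "SYNH_003")))))
  expect_true(file.exists(file.path(d1, "SYNH_003", "exam", "anat",
                                    "resection_mask.nii.gz")))
  expect_false(dir.exists(file.path(d1, "SYNH_001", "exam", "anat")))
  expect_equal(gt$pathology_shift_sd, 3)
  expect_equal(gt$pathological_rois, 17L)

  # refuse to clobber without overwrite
  expect_error(generate_cohort(cc, d1), "not empty")

  # byte-identical ground truth on regeneration
  d2 <- tempfile("cohort")
  generate_cohort(cc, d2, write_recordings = FALSE)
  expect_identical(unname(tools::md5sum(file.path(d1, "ground_truth.json"))),
                   unname(tools::md5sum(file.path(d2, "ground_truth.json"))))
  unlink(c(d1, d2), recursive = TRUE)
})
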