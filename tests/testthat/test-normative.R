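BANDS <- band_scheme()

test_that("pathology exclusion reproduces the printed example", {
  t1 <- table1_fixture(); t2 <- table2_fixture()
  tbl <- merge(t1, t2, by = "name", sort = FALSE)
  kept <- exclude_pathological(tbl)
  expect_setequal(kept, paste0("LHIPP", 6:10))
  tr <- attr(kept, "trace")
  expect_equal(tr$n_pathological, 5)

  clean <- tbl
  clean[, c("is_resected", "is_spiking", "is_structurally_abnormal",
            "is_within_soz")] <- FALSE
  expect_setequal(exclude_pathological(clean), tbl$name)

  # unassigned channels are dropped even with all-false flags
  clean$roi_id[1] <- NA
  expect_false("LHIPP1" %in% exclude_pathological(clean))
})

test_that("noisy-channel detection matches the robust-z oracle", {
  set.seed(11)
  x <- matrix(rnorm(11 * 2000), nrow = 11)
  x[7, ] <- x[7, ] * 10
  rownames(x) <- paste0("c", 1:11)
  expect_identical(detect_noisy_channels(x), "c7")

  # symmetric outliers are both caught
  y <- matrix(rnorm(11 * 2000), nrow = 11)
  y[2, ] <- y[2, ] * 10; y[9, ] <- y[9, ] / 10
  rownames(y) <- paste0("c", 1:11)
  expect_setequal(detect_noisy_channels(y), c("c2", "c9"))

  set.seed(5)
  z <- matrix(rnorm(11 * 4000), nrow = 11)
  rownames(z) <- paste0("c", 1:11)
  expect_length(detect_noisy_channels(z), 0)

  expect_error(detect_noisy_channels(matrix(rnorm(200), nrow = 2)),
               "three channels")
})

test_that("preprocessing implements the re-reference arithmetic", {
  seg <- make_segment(rbind(rep(1, 1000), rep(2, 1000)), fs = 100)
  pp <- preprocess_params(bandpass = NULL, notch_base = 60, target_fs = 100)
  out <- preprocess_segment(seg, pp)
  expect_equal(out$data[1, ], rep(-0.5, 1000))
  expect_equal(out$data[2, ], rep(0.5, 1000))

  set.seed(5)
  seg2 <- make_segment(matrix(rnorm(4 * 4000), nrow = 4), fs = 200)
  out2 <- preprocess_segment(seg2, preprocess_params(target_fs = 200))
  expect_lt(max(abs(colMeans(out2$data))), 1e-10)
})

test_that("notch kills the mains line without touching the passband", {
  fs <- 256
  t <- seq(1 / fs, 70, by = 1 / fs)
  seg <- make_segment(rbind(sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t),
                            0.7 * sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t)),
                      fs = fs)
  pp <- preprocess_params(reference = "none", bandpass = c(1, 80),
                          notch_base = 50, target_fs = 200)
  out <- preprocess_segment(seg, pp)
  expect_equal(out$fs, 200)
  expect_equal(out$duration, 70, tolerance = 1 / 200)
  w0 <- welch_psd(seg$data, fs); w1 <- welch_psd(out$data, 200)
  at <- function(w, f) w$psd[1, which.min(abs(w$freq - f))]
  expect_gt(10 * log10(at(w0, 50) / at(w1, 50)), 20)
  expect_lt(abs(10 * log10(at(w0, 10) / at(w1, 10))), 1)
})

test_that("preprocessing rejects impossible requests", {
  seg <- make_segment(matrix(rnorm(2 * 1000), nrow = 2), fs = 100)
  expect_error(preprocess_segment(seg, preprocess_params(target_fs = 200)),
               "upsampling")
  expect_error(preprocess_params(bandpass = c(1, 60), target_fs = 100),
               "Nyquist")
})

test_that("relative band powers are an exact partition of unity", {
  set.seed(9)
  sig <- generate_signal(matrix(c(0.3, 0.3, 0.15, 0.15, 0.1), 1), 70, 200,
                         seed = 2)
  rbp <- band_log_rbp(sig, BANDS, fs = 200)
  expect_lt(abs(sum(rbp$rbp) - 1), 1e-12)

  # pure alpha tone
  t <- seq(1 / 200, 70, by = 1 / 200)
  tone <- band_log_rbp(matrix(sin(2 * pi * 10 * t), 1), BANDS, fs = 200)
  expect_gt(tone$rbp[tone$band == "alpha"], 0.9)
  expect_gt(tone$log_rbp[tone$band == "alpha"], -0.046)

  # flat channel: NA marker, never -Inf
  flat <- band_log_rbp(matrix(0, 1, 14000), BANDS, fs = 200)
  expect_true(all(is.na(flat$rbp)))
  expect_false(any(is.infinite(flat$log_rbp), na.rm = TRUE))
})

test_that("white noise splits power by bandwidth", {
  props <- t(vapply(1:10, function(s) {
    set.seed(s)
    rbp <- band_log_rbp(matrix(rnorm(70 * 200), 1), BANDS, fs = 200)
    rbp$rbp
  }, numeric(5)))
  expected <- (BANDS$high - BANDS$low) / (max(BANDS$high) - min(BANDS$low))
  se <- apply(props, 2, sd) / sqrt(nrow(props))
  expect_true(all(abs(colMeans(props) - expected) < 3 * se + 1e-3))
})

test_that("regional aggregation averages RBP then logs", {
  tbl <- data.frame(channel = c("a", "b"), band = "delta",
                    rbp = c(0.2, 0.4), log_rbp = log10(c(0.2, 0.4)))
  agg <- aggregate_to_roi(tbl, c(a = 17L, b = 17L))
  expect_equal(agg$rbp, 0.3)
  expect_equal(agg$log_rbp, -0.5229, tolerance = 1e-4)

  # single-channel parcel passes through
  one <- aggregate_to_roi(tbl[1, ], c(a = 39L))
  expect_equal(one$rbp, 0.2)

  # random tables match a brute-force group-by
  set.seed(4)
  n <- 30
  tbl2 <- data.frame(channel = paste0("c", 1:n),
                     band = sample(BANDS$band, n, TRUE),
                     rbp = runif(n))
  tbl2 <- do.call(rbind, lapply(BANDS$band, function(b) {
    d <- tbl2; d$band <- b; d$rbp <- runif(n); d
  }))
  tbl2$log_rbp <- log10(tbl2$rbp)
  roi_map <- setNames(sample(c(17L, 39L, 53L), n, TRUE), paste0("c", 1:n))
  agg2 <- aggregate_to_roi(tbl2, roi_map)
  for (r in unique(agg2$roi_id)) for (b in BANDS$band) {
    manual <- mean(tbl2$rbp[roi_map[tbl2$channel] == r & tbl2$band == b])
    expect_equal(agg2$rbp[agg2$roi_id == r & agg2$band == b], manual)
  }
  expect_error(aggregate_to_roi(tbl, c(a = 17L)), "mapped")
})

test_that("leave-one-out filter removes the planted extreme only", {
  rows <- data.frame(subject_id = sprintf("S%02d", 1:31), roi_id = 17L,
                     band = "delta", log_rbp = c(rep(0, 30), 10))
  out <- loo_outlier_filter(rows)
  expect_equal(nrow(out), 30)
  expect_false("S31" %in% out$subject_id)
  expect_identical(attr(out, "removed")$subject_id, "S31")

  # degenerate spread: nothing removed, no infinities
  same <- data.frame(subject_id = sprintf("S%02d", 1:10), roi_id = 17L,
                     band = "delta", log_rbp = 1)
  expect_equal(nrow(loo_outlier_filter(same)), 10)

  # idempotence at the fixed point
  again <- loo_outlier_filter(out)
  expect_equal(nrow(again), nrow(out))

  # matches the direct leave-one-out oracle on random data (single pass)
  set.seed(8)
  r2 <- data.frame(subject_id = sprintf("S%02d", 1:40), roi_id = 39L,
                   band = "alpha", log_rbp = rnorm(40))
  z <- oracle_loo_z(r2$log_rbp)
  first_pass_removed <- r2$subject_id[abs(z) > 3]
  out2 <- loo_outlier_filter(r2, max_iter = 1)
  expect_setequal(setdiff(r2$subject_id, out2$subject_id), first_pass_removed)
})

test_that("the normative map recovers known parameters and enforces n", {
  mu <- matrix(seq(-0.9, -0.1, length.out = 10), nrow = 2, byrow = TRUE,
               dimnames = list(c("17", "39"), BANDS$band))
  rows <- simulate_normative_rows(50, mu, sd = 0.1, seed = 13)
  map <- build_normative_map(rows, min_n = 30, config_hash = "h1")
  expect_true(all(map$n >= 30))
  md <- as.data.frame(map)
  truth <- mu[cbind(as.character(md$roi_id), md$band)]
  expect_true(all(abs(md$mean_log_rbp - truth) < 3 * 0.1 / sqrt(md$n)))
  expect_true(all(abs(md$sd_log_rbp - 0.1) / 0.1 < 0.25))

  # a 29-subject parcel is dropped
  rows29 <- simulate_normative_rows(29, mu["17", , drop = FALSE], sd = 0.1,
                                    seed = 2)
  rows29$roi_id <- 53L
  map2 <- build_normative_map(rbind(rows, rows29), min_n = 30)
  expect_false(53L %in% map2$roi_id)
  expect_error(build_normative_map(rows29, min_n = 30), "min_n")

  # provenance hash follows the configuration
  p1 <- preprocess_params(); p2 <- preprocess_params(notch_base = 50)
  expect_identical(normkit:::metric_config_hash(p1, BANDS),
                   normkit:::metric_config_hash(preprocess_params(), BANDS))
  expect_false(identical(normkit:::metric_config_hash(p1, BANDS),
                         normkit:::metric_config_hash(p2, BANDS)))
})

test_that("one segment per subject is enforced before mapping", {
  mu <- matrix(-0.5, 1, 5, dimnames = list("17", BANDS$band))
  r1 <- simulate_normative_rows(35, mu, sd = 0.1, seed = 3)
  r2 <- r1; r2$segment_number <- 2L; r2$log_rbp <- r2$log_rbp + 5
  map <- build_normative_map(rbind(r1, r2), min_n = 30, z_max = NULL)
  # backup segments (with the +5 shift) must not contaminate the map
  expect_lt(abs(as.data.frame(map)$mean_log_rbp[1] + 0.5), 0.2)
})
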