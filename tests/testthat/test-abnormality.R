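BANDS <- band_scheme()

toy_map <- function(mean = -0.5, sd = 0.1, rois = c(17L, 39L)) {
  df <- expand.grid(roi_id = rois, band = BANDS$band,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean_log_rbp <- mean; df$sd_log_rbp <- sd; df$n <- 40L
  structure(df, class = c("normative_map", "data.frame"),
            config_hash = "cfg1")
}

test_that("z-scores implement (x - mean) / sd with strict provenance", {
  map <- toy_map(mean = 2, sd = 0.5, rois = 17L)
  rows <- data.frame(roi_id = 17L, band = BANDS$band, log_rbp = 3)
  z <- zscores(rows, map)
  expect_equal(z$z, rep(2, 5))

  rows0 <- data.frame(roi_id = 17L, band = BANDS$band, log_rbp = 2)
  expect_equal(zscores(rows0, map)$z, rep(0, 5))

  # unscored parcels are reported, not silently dropped
  rows2 <- rbind(rows, data.frame(roi_id = 99L, band = "delta", log_rbp = 0))
  z2 <- zscores(rows2, map)
  expect_identical(attr(z2, "unscored_rois"), 99L)

  attr(rows, "config_hash") <- "other"
  expect_error(zscores(rows, map), "hash")

  bad <- toy_map(rois = 17L); bad$sd_log_rbp <- 0
  expect_error(zscores(rows0, bad), "zero normative SD")
})

test_that("z-scores of in-distribution draws are standard normal", {
  map <- toy_map(rois = 17L)
  md <- as.data.frame(map)
  set.seed(101)
  x <- rnorm(1000, md$mean_log_rbp[1], md$sd_log_rbp[1])
  rows <- data.frame(roi_id = 17L, band = "delta", log_rbp = x)
  z <- zscores(rows, map)$z
  expect_lt(abs(mean(z)), 3 / sqrt(1000))
  expect_gt(var(z), 0.85); expect_lt(var(z), 1.15)
})

test_that("regional abnormality is the max |z| over bands", {
  z <- data.frame(roi_id = 17L, band = BANDS$band,
                  log_rbp = 0, z = c(0.5, -2, 1, 0, 0.3))
  ab <- regional_abnormality(z)
  expect_equal(ab$abnormality, 2)
  expect_identical(ab$band, BANDS$band[2])

  z0 <- z; z0$z <- 0
  expect_equal(regional_abnormality(z0)$abnormality, 0)

  # invariance under band permutation
  perm <- z[sample(nrow(z)), ]
  expect_equal(regional_abnormality(perm)$abnormality, 2)
})

test_that("region labels follow the strict >25% rule", {
  tbl <- data.frame(roi_id = rep(17L, 10),
                    is_resected = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_identical(label_resected_regions(tbl)$label, "resected")

  tbl2 <- data.frame(roi_id = rep(17L, 4),
                     is_resected = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(label_resected_regions(tbl2)$label, "spared") # exactly 25%

  t1 <- table1_fixture(); t2 <- table2_fixture()
  lab <- label_resected_regions(merge(t1, t2, by = "name"))
  expect_identical(unique(lab$label), "spared")
})

test_that("D_RS matches enumeration, complement and rank invariance", {
  expect_equal(drs(setNames(c(3, 2.5, 1, 2, 0.5), 1:5),
                   setNames(c("resected", "resected", "spared", "spared",
                              "spared"), 1:5)), 1)
  expect_equal(drs(setNames(c(1, 1), 1:2),
                   setNames(c("resected", "spared"), 1:2)), 0.5)
  expect_equal(drs(setNames(c(0.9, 0.2, 0.5, 0.4), 1:4),
                   setNames(c("resected", "resected", "spared", "spared"),
                            1:4)), 0.5)
  expect_error(drs(setNames(1, "a"), setNames("spared", "a")), "no scored")

  set.seed(55)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    scores <- setNames(round(rnorm(n), 2), seq_len(n)) # rounding forces ties
    lab <- setNames(sample(c("resected", "spared"), n, TRUE), seq_len(n))
    if (length(unique(lab)) < 2) next
    d <- drs(scores, lab)
    expect_equal(d, oracle_auc(scores[lab == "resected"],
                               scores[lab == "spared"]))
    # tie-corrected complement
    flipped <- setNames(ifelse(lab == "resected", "spared", "resected"),
                        names(lab))
    expect_equal(d + drs(scores, flipped), 1)
    # invariance under strictly increasing transforms
    expect_equal(drs(exp(scores), lab), d)
    expect_equal(drs(3 * scores + 7, lab), d)
  }
})

test_that("score_subject assembles the full abnormality result", {
  map <- toy_map()
  rows <- data.frame(roi_id = rep(c(17L, 39L), each = 5),
                     band = rep(BANDS$band, 2),
                     log_rbp = c(rep(-0.5 + 0.4, 5), rep(-0.5, 5)))
  tbl <- data.frame(roi_id = rep(c(17L, 39L), each = 2),
                    is_resected = c(TRUE, TRUE, FALSE, FALSE))
  res <- score_subject(rows, map, channel_table = tbl)
  expect_equal(res$d_rs, 1) # shifted parcel is the resected one
  expect_equal(res$abnormality$abnormality[res$abnormality$roi_id == 17L], 4)
})
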