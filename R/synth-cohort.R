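# Cohort-level synthesis: per-subject spectral identity, on-disk layout,
# ground truth.

# Per-subject, per-channel oscillatory band-power profiles and channel kinds.
# Between-subject variation is lognormal at ROI level (sigma_log in log10
# units), channel-in-ROI jitter is lognormal sigma 0.03. Held-out (test)
# subjects get the pathology multiplier on `pathology_band` for every
# pathological ROI, chosen so the shifted band's *relative* power moves by
# 10^(shift * sigma_log) after renormalisation.
subject_channel_model <- function(config, subject_index,
                                  geometry = generate_geometry(
                                    config, seed = derive_seed(config$seed, "geom", subject_index))) {
  bands <- config$bands$band
  base <- config$band_power_profile
  chans <- geometry$channels
  test <- is_test_subject(config, subject_index)
  with_seed(derive_seed(config$seed, "model", subject_index), {
    rois <- sort(unique(chans$true_roi))
    eps <- matrix(stats::rnorm(length(rois) * length(bands), 0, config$sigma_log),
                  nrow = length(rois), dimnames = list(as.character(rois), bands))
    profiles <- matrix(0, nrow = nrow(chans), ncol = length(bands),
                       dimnames = list(chans$name, bands))
    for (i in seq_len(nrow(chans))) {
      roi <- as.character(chans$true_roi[i])
      p <- base[roi, ] * 10^(eps[roi, ] + stats::rnorm(length(bands), 0, 0.03))
      if (test && chans$true_roi[i] %in% config$pathological_rois) {
        b <- config$pathology_band
        r <- p[b] / sum(p)
        ratio <- 10^(config$pathology_shift_sd * config$sigma_log)
        assert_that(r * ratio < 1,
                    "pathology shift pushes relative band power past 1")
        p[b] <- p[b] * ratio * (1 - r) / (1 - r * ratio)
      }
      profiles[i, ] <- p / sum(p)
    }
    kind <- rep("clean", nrow(chans))
    u <- stats::runif(nrow(chans))
    kind[u < config$artifact_channel_fraction] <- "artifact"
    kind[u >= config$artifact_channel_fraction &
         u < config$artifact_channel_fraction + config$spiking_channel_fraction] <- "spiking"
    list(profiles = profiles, channel_kind = kind, geometry = geometry,
         roi_eps = eps)
  })
}

cohort_exam_date <- "2024-03-04"

subject_exam_dir <- function(out_dir, subject_id) {
  file.path(out_dir, subject_id, "exam", "icEEG", cohort_exam_date)
}

write_recording_chunk <- function(data, fs, start, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  writeBin(as.vector(t(data)), con, size = 4L, endian = "little")
  close(con)
  write_json_file(list(format = "normkit-chunk-v1", n_channels = nrow(data),
                       n_samples = ncol(data), fs = fs, start = start,
                       dtype = "float32"), paste0(stem, ".json"))
  invisible(stem)
}

read_recording_chunk <- function(stem) {
  meta <- read_json_file(paste0(stem, ".json"))
  assert_that(identical(meta$format, "normkit-chunk-v1"), "not a recording chunk")
  con <- file(paste0(stem, ".dat"), "rb")
  vec <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
                 size = 4L, endian = "little")
  close(con)
  list(data = matrix(vec, nrow = meta$n_channels, byrow = TRUE),
       fs = meta$fs, start = meta$start)
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per subject, an annotated exam timeline, recording files on the
#' timeline's file schedule, channel coordinates, and (for held-out test
#' subjects) a resection mask over the pathological ROIs; plus a shared toy
#' parcellation and a ground-truth record at the cohort root. Layout follows
#' the `<subject>/exam/icEEG/<date>/` folder convention.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param write_recordings write the recording chunk files (disable to
#'   produce a metadata-only cohort).
#' @return the ground-truth record, invisibly (also written as
#'   `ground_truth.json`).
#' @export
generate_cohort <- function(config, out_dir, overwrite = FALSE,
                            write_recordings = TRUE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    if (!overwrite)
      abort_normkit(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                            out_dir), "normkit_exists")
    unlink(out_dir, recursive = TRUE) # no stale subjects from earlier cohorts
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ids <- subject_ids(config)
  geom0 <- generate_geometry(config, seed = derive_seed(config$seed, "geom", 1L))
  write_nifti(geom0$parc$labels, geom0$parc$affine,
              file.path(out_dir, "parcellation.nii.gz"), dtype = "int32")

  gt_subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    geom <- generate_geometry(config, seed = derive_seed(config$seed, "geom", s),
                              resected_rois = if (is_test_subject(config, s))
                                config$pathological_rois else integer())
    model <- subject_channel_model(config, s, geom)
    tl <- generate_timeline(config, s)
    edir <- subject_exam_dir(out_dir, ids[s])
    dir.create(edir, recursive = TRUE, showWarnings = FALSE)
    write_timeline(tl, file.path(edir, "timeline.json"))
    utils::write.csv(geom$channels[, c("name", "x", "y", "z",
                                       "electrode_type", "hemisphere")],
                     file.path(edir, "channels.csv"), row.names = FALSE)
    if (write_recordings && nrow(tl$files)) {
      rdir <- file.path(edir, "raw-eeg")
      dir.create(rdir, showWarnings = FALSE)
      for (f in seq_len(nrow(tl$files))) {
        sig <- generate_signal(
          model$profiles, duration = tl$files$end[f] - tl$files$start[f],
          fs = tl$files$fs[f], line_noise_hz = config$line_noise_hz,
          seed = derive_seed(config$seed, "rec", s, f),
          channel_kind = model$channel_kind,
          oscillation_fraction = config$oscillation_fraction,
          bands = config$bands)
        write_recording_chunk(sig, tl$files$fs[f], tl$files$start[f],
                              file.path(rdir, tl$files$path[f]))
      }
    }
    if (!is.null(geom$mask)) {
      adir <- file.path(out_dir, ids[s], "exam", "anat")
      dir.create(adir, recursive = TRUE, showWarnings = FALSE)
      write_nifti(geom$mask, geom$parc$affine,
                  file.path(adir, "resection_mask.nii.gz"), dtype = "uint8")
    }
    # true interictal intervals: exam minus the default 2 h buffer
    span <- intervals(0, exam_span(tl))
    if (nrow(tl$seizures)) {
      buf <- intervals(tl$seizures$onset - 7200,
                       tl$seizures$onset + tl$seizures$duration + 7200)
      span <- interval_subtract(span, buf)
    }
    gt_subjects[[s]] <- list(
      subject_id = ids[s],
      test_subject = is_test_subject(config, s),
      interictal_intervals = span,
      artifact_channels = geom$channels$name[model$channel_kind == "artifact"],
      spiking_channels = geom$channels$name[model$channel_kind == "spiking"],
      channel_true_roi = stats::setNames(geom$channels$true_roi,
                                         geom$channels$name),
      resected_rois = if (is_test_subject(config, s))
        config$pathological_rois else integer()
    )
  }

  gt <- list(
    format = "normkit-ground-truth-v1",
    seed = config$seed,
    sigma_log = config$sigma_log,
    pathology_shift_sd = config$pathology_shift_sd,
    pathology_band = config$pathology_band,
    pathological_rois = config$pathological_rois,
    roi_mean_log_rbp = log10(config$band_power_profile),
    subjects = gt_subjects
  )
  write_json_file(gt, file.path(out_dir, "ground_truth.json"))
  write_json_file(cohort_config_to_list(config),
                  file.path(out_dir, "cohort_config.json"))
  invisible(gt)
}

cohort_config_to_list <- function(config) {
  x <- unclass(config)
  x$band_power_profile <- apply(config$band_power_profile, 1L, as.list,
                                simplify = FALSE)
  x$bands <- NULL
  x
}

cohort_config_from_list <- function(x) {
  prof <- do.call(rbind, lapply(x$band_power_profile, function(r) unlist(r)))
  rownames(prof) <- names(x$band_power_profile)
  x$band_power_profile <- prof
  x$seizure_type_mix <- unlist(x$seizure_type_mix)
  x$pathological_rois <- as.integer(unlist(x$pathological_rois) %||% integer())
  do.call(cohort_config, x[intersect(names(x), names(formals(cohort_config)))])
}

read_cohort_config <- function(dir) {
  cohort_config_from_list(read_json_file(file.path(dir, "cohort_config.json")))
}

#' Simulate a regional metric table directly
#'
#' Fast path for testing the regional aggregation machinery: draws
#' subject-by-ROI-by-band log10(RBP) values i.i.d. from
#' Normal(`mean_log_rbp`, `sd`), skipping signal synthesis entirely. Values
#' are not constrained to the RBP simplex.
#'
#' @param n_subjects number of subjects.
#' @param mean_log_rbp rois x bands matrix of true means (rownames = ROI
#'   ids, colnames = band names).
#' @param sd common SD.
#' @param seed integer seed.
#' @param hospital hospital code used for subject ids.
#' @return data.frame subject_id / roi_id / band / log_rbp / segment_number.
#' @export
simulate_normative_rows <- function(n_subjects, mean_log_rbp, sd = 0.1,
                                    seed = 1L, hospital = "SYNH") {
  rois <- rownames(mean_log_rbp)
  bands <- colnames(mean_log_rbp)
  with_seed(derive_seed(seed, "metric-rows"), {
    grid <- expand.grid(band = bands, roi_id = rois,
                        subject = seq_len(n_subjects),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- mean_log_rbp[cbind(grid$roi_id, grid$band)]
    data.frame(
      subject_id = sprintf("%s_%03d", hospital, grid$subject),
      roi_id = as.integer(grid$roi_id),
      band = grid$band,
      log_rbp = stats::rnorm(nrow(grid), mu, sd),
      segment_number = 1L,
      stringsAsFactors = FALSE)
  })
}
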