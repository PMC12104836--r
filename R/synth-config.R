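# Synthetic cohort configuration and the stated generative world.

#' Default regional band-power archetypes
#'
#' Relative oscillatory band power for each synthetic parcel. Interictal
#' icEEG is delta-dominant with regional flavour: hippocampus theta-rich,
#' amygdala delta-heavy, temporal neocortex alpha-leaning, frontal cortex
#' beta-leaning. Rows sum to 1.
#'
#' @param roi_ids integer label ids (defaults to the grey parcels of
#'   [dk_label_map()]).
#' @return matrix rois x bands of relative oscillatory power.
#' @export
default_band_profiles <- function(roi_ids = NULL) {
  lm <- dk_label_map()
  grey <- lm[lm$tissue == "grey", ]
  if (is.null(roi_ids)) roi_ids <- grey$label
  archetype <- function(name) {
    if (grepl("Hippocampus", name)) c(0.30, 0.30, 0.15, 0.15, 0.10)
    else if (grepl("Amygdala", name)) c(0.40, 0.25, 0.12, 0.13, 0.10)
    else if (grepl("middle-temporal", name)) c(0.28, 0.18, 0.28, 0.16, 0.10)
    else c(0.30, 0.15, 0.15, 0.28, 0.12)
  }
  bands <- band_scheme()$band
  out <- t(vapply(roi_ids, function(id) {
    nm <- lm$roi_name[match(id, lm$label)]
    archetype(if (is.na(nm)) "" else nm)
  }, numeric(length(bands))))
  dimnames(out) <- list(as.character(roi_ids), bands)
  out
}

#' Construct a synthetic cohort configuration
#'
#' Defines the stated world the generator draws from: cohort size, recording
#' geometry, exam timeline statistics, spectral structure, pathology and
#' artifact injection. All downstream synthetic data are a deterministic
#' function of this object.
#'
#' @param n_subjects number of normative subjects.
#' @param n_test_subjects held-out subjects carrying the pathology shift and
#'   a resection mask over `pathological_rois`.
#' @param n_channels electrode contacts per subject (distributed round-robin
#'   over the eight synthetic depth electrodes).
#' @param sampling_rate recording sampling frequency, Hz.
#' @param exam_duration exam length, hours.
#' @param seizure_rate seizure events per day (Poisson).
#' @param seizure_type_mix named proportions over focal/subclin/sg; must sum
#'   to 1.
#' @param band_power_profile rois x bands relative oscillatory power matrix
#'   (default [default_band_profiles()]).
#' @param pathological_rois integer parcel ids shifted in the held-out
#'   subjects.
#' @param pathology_shift_sd size of the pathological log-RBP shift in units
#'   of `sigma_log` (default +3 SD).
#' @param pathology_band band receiving the shift (default `"gamma"`:
#'   epileptogenic tissue expresses excess fast activity, and the gamma band
#'   is least diluted by the 1/f background).
#' @param sigma_log between-subject SD of log10 band power.
#' @param artifact_channel_fraction,spiking_channel_fraction expected
#'   fractions of injected bad/spiking channels.
#' @param line_noise_hz mains frequency, 50 or 60.
#' @param oscillation_fraction fraction of clean-channel variance carried by
#'   the band-limited oscillations (the rest is 1/f background + line noise).
#' @param recording_chunk_s length of each synthetic recording file, seconds.
#' @param hospital four-letter hospital code for subject ids.
#' @param seed integer master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10,
                          n_test_subjects = 0,
                          n_channels = 16,
                          sampling_rate = 200,
                          exam_duration = 120,
                          seizure_rate = 2,
                          seizure_type_mix = c(focal = 0.5, subclin = 0.4, sg = 0.1),
                          band_power_profile = NULL,
                          pathological_rois = integer(),
                          pathology_shift_sd = 3,
                          pathology_band = "gamma",
                          sigma_log = 0.1,
                          artifact_channel_fraction = 0.05,
                          spiking_channel_fraction = 0.1,
                          line_noise_hz = 60,
                          oscillation_fraction = 0.85,
                          recording_chunk_s = 90,
                          hospital = "SYNH",
                          seed = 1L) {
  bands <- band_scheme()
  if (is.null(band_power_profile)) band_power_profile <- default_band_profiles()
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(abs(sum(seizure_type_mix) - 1) < 1e-9,
              "seizure_type_mix proportions must sum to 1")
  assert_that(all(sort(names(seizure_type_mix)) == sort(c("focal", "subclin", "sg"))),
              "seizure_type_mix must be named focal/subclin/sg")
  assert_that(sampling_rate > 2 * max(bands$high),
              "sampling_rate must exceed twice the highest band edge")
  assert_that(line_noise_hz %in% c(50, 60), "line_noise_hz must be 50 or 60")
  assert_that(pathology_band %in% bands$band, "unknown pathology_band")
  assert_that(abs(sum(rowSums(band_power_profile) - 1)) < 1e-6,
              "band_power_profile rows must sum to 1")
  assert_that(exam_duration > 0, "exam_duration must be positive")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_test_subjects = as.integer(n_test_subjects),
    n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate,
    exam_duration = exam_duration,
    seizure_rate = seizure_rate,
    seizure_type_mix = seizure_type_mix,
    band_power_profile = band_power_profile,
    pathological_rois = as.integer(pathological_rois),
    pathology_shift_sd = pathology_shift_sd,
    pathology_band = pathology_band,
    sigma_log = sigma_log,
    artifact_channel_fraction = artifact_channel_fraction,
    spiking_channel_fraction = spiking_channel_fraction,
    line_noise_hz = line_noise_hz,
    oscillation_fraction = oscillation_fraction,
    recording_chunk_s = recording_chunk_s,
    hospital = hospital,
    bands = bands,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d normative + %d test subjects, %d ch @ %g Hz, %g h exam, seed %d\n",
    x$n_subjects, x$n_test_subjects, x$n_channels, x$sampling_rate,
    x$exam_duration, x$seed))
  invisible(x)
}

subject_ids <- function(config) {
  n <- config$n_subjects + config$n_test_subjects
  sprintf("%s_%03d", config$hospital, seq_len(n))
}

is_test_subject <- function(config, subject_index) {
  subject_index > config$n_subjects
}
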