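# End-to-end orchestration: simulate -> select -> localise -> db -> map ->
# score, with a manifest and a step-trace log.

PIPELINE_STAGES <- c("simulate", "select", "localise", "db", "map", "score")

#' Construct a run configuration
#'
#' Single source of truth for every decision-point parameter of a pipeline
#' run. Unknown keys are rejected.
#'
#' @param cohort a [cohort_config()] (the synthetic world).
#' @param policy a [selection_policy()] (temporal decision points).
#' @param preprocess a [preprocess_params()] (signal conditioning).
#' @param bands a [band_scheme()].
#' @param max_grey_dist,resect_dist localisation thresholds, mm.
#' @param min_n minimum subjects per normative parcel-band row.
#' @param loo_z_max leave-one-out outlier threshold.
#' @param score_noisy_z_max conservative noisy-channel threshold used when
#'   scoring (spiking must not be excluded).
#' @param resect_threshold resected-region channel proportion.
#' @param keep_recordings keep raw recording chunks after extraction.
#' @param seed master seed (overrides `cohort$seed`).
#' @param ... rejected; catches misspelled keys.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), policy = selection_policy(),
                       preprocess = NULL, bands = band_scheme(),
                       max_grey_dist = 5, resect_dist = 5,
                       min_n = 30, loo_z_max = 3,
                       score_noisy_z_max = 5, resect_threshold = 0.25,
                       keep_recordings = TRUE, seed = NULL, ...) {
  extra <- list(...)
  assert_that(length(extra) == 0,
              sprintf("unknown config key(s): %s",
                      paste(names(extra), collapse = ", ")))
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  if (is.null(preprocess))
    preprocess <- preprocess_params(notch_base = cohort$line_noise_hz)
  structure(list(cohort = cohort, policy = policy, preprocess = preprocess,
                 bands = bands, max_grey_dist = max_grey_dist,
                 resect_dist = resect_dist, min_n = min_n,
                 loo_z_max = loo_z_max,
                 score_noisy_z_max = score_noisy_z_max,
                 resect_threshold = resect_threshold,
                 keep_recordings = keep_recordings),
            class = "run_config")
}

run_config_hash <- function(config) {
  x <- unclass(config)
  x$cohort <- cohort_config_to_list(config$cohort)
  x$policy <- unclass(config$policy)
  x$preprocess <- unclass(config$preprocess)
  x$bands <- as.data.frame(config$bands)
  md5_string(canonical_json(x))
}

# Channel disposition for one subject: every channel lands in exactly one
# bucket (mirrors the filtering order pathological -> unsuitable ->
# unlocalised -> noisy -> retained).
channel_accounting <- function(all_names, pathological, unsuitable,
                               unlocalised, noisy) {
  reason <- rep("retained", length(all_names))
  names(reason) <- all_names
  reason[all_names %in% noisy] <- "noisy"
  reason[all_names %in% unlocalised] <- "unlocalised"
  reason[all_names %in% unsuitable] <- "unsuitable"
  reason[all_names %in% pathological] <- "pathological"
  reason
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in dependency order (segment selection and
#' localisation are independent of one another and commute). Writes every
#' artifact under `out_dir` plus a manifest of produced files (with md5
#' hashes and the config hash) and a machine-readable step-trace log.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("simulate", "select", "localise", "db", "map", "score")` or
#'   `"all"`.
#' @param overwrite passed to [generate_cohort()].
#' @return the manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, stages = "all", overwrite = FALSE) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  assert_that(all(stages %in% PIPELINE_STAGES),
              sprintf("unknown stage(s): %s",
                      paste(setdiff(stages, PIPELINE_STAGES), collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  deps <- list(select = "simulate", localise = "simulate",
               db = c("select", "localise"), map = "db", score = "map")
  cohort_dir <- file.path(out_dir, "cohort")
  have <- function(stage) {
    switch(stage,
      simulate = file.exists(file.path(cohort_dir, "ground_truth.json")),
      select = length(Sys.glob(file.path(cohort_dir, "*", "exam", "icEEG",
                                         "*", "eeg-segments"))) > 0,
      localise = length(Sys.glob(file.path(cohort_dir, "*", "channel_table.csv"))) > 0,
      db = file.exists(file.path(out_dir, "db", "subject.json")),
      map = file.exists(file.path(out_dir, "normative_map.csv")),
      FALSE)
  }
  for (st in stages) {
    for (d in deps[[st]] %||% character()) {
      if (!d %in% stages && !have(d))
        abort_normkit(sprintf("stage '%s' requires upstream stage '%s'", st, d),
                      "normkit_dependency")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace <- list()
  cc <- config$cohort

  if ("simulate" %in% stages) {
    generate_cohort(cc, cohort_dir, overwrite = overwrite)
    trace$simulate <- list(n_subjects = cc$n_subjects + cc$n_test_subjects)
  }

  gt <- read_json_file(file.path(cohort_dir, "ground_truth.json"))
  ids <- vapply(gt$subjects$subject_id, identity, character(1))
  test_flag <- gt$subjects$test_subject
  exam_dirs <- vapply(ids, function(id) subject_exam_dir(cohort_dir, id),
                      character(1))

  if ("select" %in% stages) {
    sel_trace <- list()
    for (s in seq_along(ids)) {
      tl <- read_timeline(file.path(exam_dirs[s], "timeline.json"))
      coords <- utils::read.csv(file.path(exam_dirs[s], "channels.csv"),
                                stringsAsFactors = FALSE)
      spiking <- unlist(gt$subjects$spiking_channels[s])
      segs <- plan_and_extract_segments(
        file.path(exam_dirs[s], "raw-eeg"), tl, config$policy,
        coords$name, known_spiking = spiking)
      sdir <- file.path(exam_dirs[s], "eeg-segments")
      dir.create(sdir, showWarnings = FALSE)
      for (k in seq_along(segs))
        write_segment(segs[[k]],
                      file.path(sdir, sprintf("interictal_segment%d", k)))
      sel_trace[[ids[s]]] <- c(attr(segs, "trace"),
                               list(n_segments = length(segs)))
      if (!config$keep_recordings)
        unlink(file.path(exam_dirs[s], "raw-eeg"), recursive = TRUE)
    }
    trace$select <- sel_trace
  }

  if ("localise" %in% stages) {
    vol <- read_nifti(file.path(cohort_dir, "parcellation.nii.gz"))
    parc <- parcellation_volume(vol$data, vol$affine)
    loc_trace <- list()
    for (s in seq_along(ids)) {
      coords <- utils::read.csv(file.path(exam_dirs[s], "channels.csv"),
                                stringsAsFactors = FALSE)
      mask_path <- file.path(cohort_dir, ids[s], "exam", "anat",
                             "resection_mask.nii.gz")
      mask <- if (file.exists(mask_path)) read_nifti(mask_path) else NULL
      flags <- data.frame(name = coords$name,
                          is_spiking = coords$name %in%
                            unlist(gt$subjects$spiking_channels[s]))
      tbl <- build_channel_table(coords, parc, mask = mask,
                                 max_grey_dist = config$max_grey_dist,
                                 resect_dist = config$resect_dist,
                                 flags = flags)
      write_channel_table(tbl, file.path(cohort_dir, ids[s],
                                         "channel_table.csv"))
      loc_trace[[ids[s]]] <- list(n_channels = nrow(tbl),
                                  n_unlocalised = sum(is.na(tbl$roi_id)))
    }
    trace$localise <- loc_trace
  }

  if ("db" %in% stages) {
    db <- db_create(file.path(out_dir, "db"),
                    hospitals = unique(c("UCLH", "GOSH", cc$hospital)))
    for (s in seq_along(ids)) {
      db_insert(db, list(hospital = cc$hospital, subject_id = ids[s]),
                "subject", flush = FALSE)
      exam_id <- paste0(ids[s], "_icEEG_1")
      db_insert(db, list(subject_id = ids[s], exam_id = exam_id,
                         exam_type = "icEEG", exam_date = cohort_exam_date,
                         raw_iceeg_folder_location =
                           file.path(ids[s], "exam", "icEEG",
                                     cohort_exam_date, "raw-eeg")),
                "exam", flush = FALSE)
      tbl <- read_channel_table(file.path(cohort_dir, ids[s],
                                          "channel_table.csv"))
      ch_docs <- lapply(seq_len(nrow(tbl)), function(i) {
        d <- list(subject_id = ids[s], exam_id = exam_id,
                  channel_name = tbl$name[i],
                  channel_hemisphere = tbl$hemisphere[i],
                  electrode_type = tbl$electrode_type[i],
                  location = c(tbl$x[i], tbl$y[i], tbl$z[i]))
        if (!is.na(tbl$roi_id[i])) {
          d$roi_ids <- tbl$roi_id[i]
          d$roi_names <- tbl$roi_name[i]
        }
        for (fl in c("is_resected", "is_spiking",
                     "is_structurally_abnormal", "is_within_soz"))
          if (!is.na(tbl[[fl]][i])) d[[fl]] <- tbl[[fl]][i]
        d
      })
      for (d in ch_docs) db_insert(db, d, "channel", flush = FALSE)
      seg_stems <- sort(Sys.glob(file.path(exam_dirs[s], "eeg-segments",
                                           "interictal_segment*.json")))
      for (stem in sub("\\.json$", "", seg_stems)) {
        seg <- read_segment(stem)
        db_insert(db, list(subject_id = ids[s], exam_id = exam_id,
                           datetime = seg$start_datetime,
                           duration = seg$duration,
                           sampling_frequency = seg$fs,
                           reference = seg$reference,
                           wake_status = seg$wake_status,
                           segment_number = seg$segment_number,
                           unsuitable_channels = seg$unsuitable_channels,
                           spiking_channels = seg$spiking_channels,
                           file_location = substring(stem, nchar(out_dir) + 2L)),
                  "iceeg_segment", flush = FALSE)
      }
      tl <- read_timeline(file.path(exam_dirs[s], "timeline.json"))
      if (nrow(tl$seizures)) {
        for (i in seq_len(nrow(tl$seizures)))
          db_insert(db, list(subject_id = ids[s], exam_id = exam_id,
                             seizure_datetime = tl$start_datetime +
                               tl$seizures$onset[i],
                             seizure_duration = tl$seizures$duration[i],
                             seizure_type = tl$seizures$type[i]),
                    "seizure", flush = FALSE)
      }
    }
    db_flush(db)
    trace$db <- list(n_docs = vapply(db$docs, length, integer(1)))
  }

  config_hash <- metric_config_hash(config$preprocess, config$bands)

  # shared metric path: segment container -> retained channels -> preprocess
  # -> log(RBP) -> regional aggregation
  subject_metric <- function(s, normative) {
    tbl <- read_channel_table(file.path(cohort_dir, ids[s],
                                        "channel_table.csv"))
    stems <- sort(Sys.glob(file.path(exam_dirs[s], "eeg-segments",
                                     "interictal_segment*.json")))
    if (!length(stems)) return(NULL)
    rows_all <- list()
    for (stem in sub("\\.json$", "", stems)) {
      seg <- read_segment(stem)
      patho <- if (normative) {
        retained_names <- exclude_pathological(tbl)
        setdiff(tbl$name, retained_names)
      } else {
        tbl$name[is.na(tbl$roi_id)] # scoring keeps pathological channels
      }
      unsuitable <- seg$unsuitable_channels
      unlocalised <- tbl$name[is.na(tbl$roi_id)]
      cand <- setdiff(seg$channel_names, union(patho, union(unsuitable,
                                                            unlocalised)))
      if (length(cand) < 3) next
      noisy <- detect_noisy_channels(
        segment_subset(seg, cand),
        z_max = if (normative) 3 else config$score_noisy_z_max)
      keep <- setdiff(cand, noisy)
      if (length(keep) < 2) next
      acct <- channel_accounting(seg$channel_names, patho, unsuitable,
                                 unlocalised, noisy)
      pp <- preprocess_segment(segment_subset(seg, keep), config$preprocess)
      rbp <- band_log_rbp(pp, config$bands)
      roi_map <- stats::setNames(tbl$roi_id, tbl$name)
      agg <- aggregate_to_roi(rbp, roi_map)
      agg$subject_id <- ids[s]
      agg$segment_number <- seg$segment_number
      attr(agg, "accounting") <- acct
      rows_all[[length(rows_all) + 1L]] <- agg
    }
    if (!length(rows_all)) return(NULL)
    out <- do.call(rbind, lapply(rows_all, function(a) a))
    attr(out, "accounting") <- attr(rows_all[[1]], "accounting")
    out
  }

  if ("map" %in% stages) {
    norm_idx <- which(!test_flag)
    rows <- list(); acct <- list()
    for (s in norm_idx) {
      r <- subject_metric(s, normative = TRUE)
      if (!is.null(r)) {
        acct[[ids[s]]] <- as.list(attr(r, "accounting"))
        rows[[length(rows) + 1L]] <- r
      }
    }
    assert_that(length(rows) > 0, "no normative subject produced a metric")
    rows <- do.call(rbind, rows)
    map <- build_normative_map(rows, min_n = config$min_n,
                               z_max = config$loo_z_max,
                               config_hash = config_hash)
    write_normative_map(map, file.path(out_dir, "normative_map.csv"))
    trace$map <- list(n_subjects = length(norm_idx),
                      n_rows = nrow(map),
                      channel_accounting = acct,
                      loo_rows_removed =
                        attr(map, "trace")$n_outlier_rows_removed %||% 0)
  }

  if ("score" %in% stages) {
    map <- read_normative_map(file.path(out_dir, "normative_map.csv"))
    test_idx <- which(test_flag)
    score_trace <- list()
    unlink(file.path(out_dir, "abnormality"), recursive = TRUE)
    dir.create(file.path(out_dir, "abnormality"), showWarnings = FALSE)
    for (s in test_idx) {
      r <- subject_metric(s, normative = FALSE)
      if (is.null(r)) next
      # one segment per subject: lowest surviving segment number
      r1 <- r[r$segment_number == min(r$segment_number), , drop = FALSE]
      attr(r1, "config_hash") <- config_hash
      tbl <- read_channel_table(file.path(cohort_dir, ids[s],
                                          "channel_table.csv"))
      res <- score_subject(r1, map, channel_table = tbl,
                           resect_threshold = config$resect_threshold)
      out_csv <- merge(res$abnormality,
                       res$labels[, c("roi_id", "label")],
                       by = "roi_id", all.x = TRUE)
      utils::write.csv(out_csv,
                       file.path(out_dir, "abnormality",
                                 paste0(ids[s], ".csv")), row.names = FALSE)
      write_json_file(list(subject_id = ids[s], d_rs = res$d_rs,
                           config_hash = config_hash),
                      file.path(out_dir, "abnormality",
                                paste0(ids[s], "_summary.json")))
      score_trace[[ids[s]]] <- list(d_rs = res$d_rs,
                                    n_rois = nrow(res$abnormality))
    }
    trace$score <- score_trace
  }

  write_json_file(trace, file.path(out_dir, "run_log.json"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(config_hash = run_config_hash(config),
                   metric_config_hash = config_hash,
                   stages = stages,
                   files = data.frame(path = files, md5 = hashes,
                                      stringsAsFactors = FALSE))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
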