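# Normative mapping: channel exclusion, preprocessing, log(RBP) metric,
# regional aggregation, leave-one-out outlier control, map assembly.

#' Construct preprocessing parameters
#'
#' Decision-point bundle for the signal conditioning applied to every
#' retained channel: re-reference, zero-phase band-pass, zero-phase notch at
#' the mains base and its harmonics inside the analysis range, and
#' anti-aliased resampling to a common rate.
#'
#' @param reference `"common_average"`, `"bipolar"` or `"none"`.
#' @param bandpass `c(low, high)` Hz (default 0.5-47.5).
#' @param notch_base mains frequency, 50 or 60 Hz.
#' @param notch_width full stop-band width per notch, Hz.
#' @param target_fs common output sampling rate, Hz (default 200; data are
#'   never upsampled).
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(reference = "common_average",
                              bandpass = c(0.5, 47.5),
                              notch_base = 60, notch_width = 2,
                              target_fs = 200) {
  assert_that(reference %in% c("common_average", "bipolar", "none"),
              "unknown reference type")
  assert_that(notch_base %in% c(50, 60), "notch_base must be 50 or 60")
  if (!is.null(bandpass)) {
    assert_that(bandpass[2] > bandpass[1] && bandpass[1] >= 0,
                "invalid bandpass")
    assert_that(bandpass[2] < target_fs / 2,
                "bandpass high edge must lie below the target Nyquist")
  }
  structure(list(reference = reference, bandpass = bandpass,
                 notch_base = notch_base, notch_width = notch_width,
                 target_fs = target_fs), class = "preprocess_params")
}

#' Drop channels representing pathology or without localisation
#'
#' Removes channels flagged resected, spiking, structurally abnormal or
#' within the seizure-onset zone (absent flags are treated as FALSE and
#' counted), and channels with no parcel assignment.
#'
#' @param channel_table a [build_channel_table()] data.frame.
#' @return character vector of retained channel names, with exclusion
#'   counts in `attr(, "trace")`.
#' @export
exclude_pathological <- function(channel_table) {
  flags <- c("is_resected", "is_spiking", "is_structurally_abnormal",
             "is_within_soz")
  patho <- rep(FALSE, nrow(channel_table))
  n_absent <- 0L
  for (fl in flags) {
    v <- channel_table[[fl]]
    if (is.null(v)) v <- rep(NA, nrow(channel_table))
    n_absent <- n_absent + sum(is.na(v))
    patho <- patho | (!is.na(v) & v)
  }
  unlocalised <- is.na(channel_table$roi_id)
  keep <- !patho & !unlocalised
  out <- channel_table$name[keep]
  attr(out, "trace") <- list(n_input = nrow(channel_table),
                             n_pathological = sum(patho),
                             n_unlocalised = sum(unlocalised & !patho),
                             n_flag_values_absent = n_absent,
                             n_retained = length(out))
  out
}

#' Algorithmic noisy-channel detection
#'
#' Flags channels whose log signal range or log variance is a robust-z
#' outlier (median/MAD across channels).
#'
#' @param segment a [segment_record()] (or channels x samples matrix).
#' @param z_max robust-z threshold (default 3; use a conservative value
#'   such as 5 when scoring subjects whose spiking channels must be kept).
#' @return character vector of flagged channel names.
#' @export
detect_noisy_channels <- function(segment, z_max = 3) {
  data <- if (inherits(segment, "segment_record")) segment$data else segment
  nm <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  assert_that(nrow(data) >= 3,
              "need at least three channels for cross-channel statistics")
  rng <- apply(data, 1L, function(x) diff(range(x)))
  vr <- apply(data, 1L, stats::var)
  eps <- .Machine$double.xmin
  z_rng <- robust_z(log10(rng + eps))
  z_var <- robust_z(log10(vr + eps))
  nm[abs(z_rng) > z_max | abs(z_var) > z_max]
}

#' Preprocess a segment
#'
#' Common-average re-reference over the retained channels, zero-phase
#' band-pass, zero-phase notch at the mains base and harmonics within the
#' band, then Fourier resampling to the common rate. Duration is preserved
#' to within one sample.
#'
#' @param segment a [segment_record()] already reduced to retained channels.
#' @param params a [preprocess_params()].
#' @return the preprocessed [segment_record()] (fs = `target_fs`).
#' @export
preprocess_segment <- function(segment, params) {
  fs <- segment$fs
  assert_that(params$target_fs <= fs, "upsampling is not supported")
  if (!is.null(params$bandpass))
    assert_that(params$bandpass[2] < fs / 2,
                "bandpass high edge at or above Nyquist")
  x <- segment$data
  if (params$reference == "common_average") {
    x <- sweep(x, 2L, colMeans(x), `-`)
  } else if (params$reference == "bipolar") {
    assert_that(nrow(x) >= 2, "bipolar reference needs at least two channels")
    x <- x[-nrow(x), , drop = FALSE] - x[-1L, , drop = FALSE]
    segment$channel_names <- paste0(segment$channel_names[-length(segment$channel_names)],
                                    "-", segment$channel_names[-1L])
  }
  if (!is.null(params$bandpass)) {
    x <- fft_bandpass(x, fs, params$bandpass[1], params$bandpass[2])
    if (params$notch_base <= params$bandpass[2] + params$notch_width)
      x <- fft_notch(x, fs, params$notch_base, width = params$notch_width,
                     max_freq = params$bandpass[2] + params$notch_width)
  } else {
    x <- fft_notch(x, fs, params$notch_base, width = params$notch_width)
  }
  x <- fft_resample(x, fs, params$target_fs)
  rownames(x) <- segment$channel_names
  segment$data <- x
  segment$fs <- params$target_fs
  segment$duration <- ncol(x) / params$target_fs
  segment
}

#' Per-channel log relative band power
#'
#' Welch PSD per channel; band power is the sum of PSD bins whose centre
#' falls in the half-open band; RBP is band power over total power across
#' the analysis range (the band union), so the five RBP values sum to 1
#' exactly before the log. Flat channels yield NA rather than -Inf.
#'
#' @param segment a preprocessed [segment_record()] (or matrix with an `fs`
#'   argument).
#' @param bands a [band_scheme()].
#' @param fs sampling rate when `segment` is a bare matrix.
#' @param window_sec,overlap Welch parameters (default 2 s Hamming, 50%).
#' @return data.frame channel / band / rbp / log_rbp (log10).
#' @export
band_log_rbp <- function(segment, bands = band_scheme(), fs = NULL,
                         window_sec = 2, overlap = 0.5) {
  if (inherits(segment, "segment_record")) {
    data <- segment$data; fs <- segment$fs
    nm <- segment$channel_names
  } else {
    data <- as.matrix(segment)
    assert_that(!is.null(fs), "fs required for matrix input")
    nm <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  }
  w <- welch_psd(data, fs, window_sec = window_sec, overlap = overlap)
  bin_band <- assign_bins(w$freq, bands)
  out <- vector("list", nrow(data))
  for (ch in seq_len(nrow(data))) {
    bp <- vapply(bands$band, function(b)
      sum(w$psd[ch, bin_band == b]), numeric(1))
    total <- sum(bp)
    rbp <- if (total > 0) bp / total else rep(NA_real_, length(bp))
    out[[ch]] <- data.frame(channel = nm[ch], band = bands$band,
                            rbp = as.numeric(rbp),
                            log_rbp = suppressWarnings(log10(as.numeric(rbp))),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate channel metrics to the regional level
#'
#' One value per implanted parcel per band: the reducer (default mean) is
#' applied to the linear RBP values of the parcel's channels, then log10 is
#' taken.
#'
#' @param rbp_table output of [band_log_rbp()].
#' @param roi_map named integer vector: channel name -> parcel id.
#' @param reducer function applied in RBP space (default `mean`).
#' @return data.frame roi_id / band / rbp / log_rbp.
#' @export
aggregate_to_roi <- function(rbp_table, roi_map, reducer = mean) {
  assert_that(all(rbp_table$channel %in% names(roi_map)),
              "every channel must be mapped to a parcel")
  rbp_table$roi_id <- as.integer(roi_map[rbp_table$channel])
  agg <- stats::aggregate(rbp ~ roi_id + band, data = rbp_table,
                          FUN = reducer)
  agg$log_rbp <- log10(agg$rbp)
  agg[order(agg$roi_id, agg$band), c("roi_id", "band", "rbp", "log_rbp")]
}

#' Iterative leave-one-out regional outlier filter
#'
#' Per parcel and band, each subject's value is z-scored against the
#' leave-one-out mean and SD of the remaining subjects; subject-parcel rows
#' with any band exceeding `z_max` in absolute value are removed, and the
#' procedure repeats to a fixed point (at most `max_iter` passes). Cells
#' with zero leave-one-out SD yield no finite z and are never flagged.
#'
#' @param rows data.frame subject_id / roi_id / band / log_rbp (one segment
#'   per subject).
#' @param z_max threshold (default 3).
#' @param max_iter iteration cap (default 10).
#' @return the retained rows, with removed subject-parcel pairs in
#'   `attr(, "removed")`.
#' @export
loo_outlier_filter <- function(rows, z_max = 3, max_iter = 10) {
  removed <- data.frame(subject_id = character(), roi_id = integer(),
                        iteration = integer(), stringsAsFactors = FALSE)
  for (it in seq_len(max_iter)) {
    flag <- rep(FALSE, nrow(rows))
    for (key in unique(paste(rows$roi_id, rows$band))) {
      idx <- which(paste(rows$roi_id, rows$band) == key)
      if (length(idx) < 3) next
      x <- rows$log_rbp[idx]
      n <- length(x)
      for (i in seq_len(n)) {
        rest <- x[-i]
        s <- stats::sd(rest)
        if (!is.finite(s)) next
        if (s == 0) {
          # zero leave-one-out spread: a value equal to the rest has no
          # finite z (0/0) and is never flagged; a deviant value is
          # unambiguously extreme
          if (x[i] != mean(rest)) flag[idx[i]] <- TRUE
        } else if (abs((x[i] - mean(rest)) / s) > z_max) flag[idx[i]] <- TRUE
      }
    }
    if (!any(flag)) break
    bad <- unique(rows[flag, c("subject_id", "roi_id")])
    bad$iteration <- it
    removed <- rbind(removed, bad)
    drop <- paste(rows$subject_id, rows$roi_id) %in%
      paste(bad$subject_id, bad$roi_id)
    rows <- rows[!drop, , drop = FALSE]
  }
  rownames(rows) <- NULL
  attr(rows, "removed") <- removed
  rows
}

#' Build the regional normative map
#'
#' Enforces one segment per subject (the lowest surviving segment number),
#' applies the leave-one-out outlier filter, then summarises each parcel
#' and band as mean/SD/n of log10(RBP) across subjects, dropping rows with
#' fewer than `min_n` subjects.
#'
#' @param rows data.frame subject_id / roi_id / band / log_rbp
#'   (+ optional segment_number).
#' @param min_n minimum subjects per retained parcel-band row (default 30).
#' @param z_max leave-one-out threshold (default 3; NULL skips the filter).
#' @param config_hash provenance hash of the metric configuration.
#' @return object of class `normative_map`: data.frame roi_id / band /
#'   mean_log_rbp / sd_log_rbp / n plus provenance attributes.
#' @export
build_normative_map <- function(rows, min_n = 30, z_max = 3,
                                config_hash = NA_character_) {
  if ("segment_number" %in% names(rows)) {
    first <- stats::aggregate(segment_number ~ subject_id, data = rows, FUN = min)
    rows <- merge(rows, first, by = c("subject_id", "segment_number"))
  }
  trace <- list(n_rows_in = nrow(rows))
  if (!is.null(z_max)) {
    rows <- loo_outlier_filter(rows, z_max = z_max)
    trace$n_outlier_rows_removed <- trace$n_rows_in - nrow(rows)
  }
  stats_df <- stats::aggregate(log_rbp ~ roi_id + band, data = rows,
                               FUN = function(x) c(mean = mean(x),
                                                   sd = stats::sd(x),
                                                   n = length(x)))
  out <- data.frame(roi_id = stats_df$roi_id, band = stats_df$band,
                    mean_log_rbp = stats_df$log_rbp[, "mean"],
                    sd_log_rbp = stats_df$log_rbp[, "sd"],
                    n = as.integer(stats_df$log_rbp[, "n"]),
                    stringsAsFactors = FALSE)
  dropped <- out[out$n < min_n, , drop = FALSE]
  out <- out[out$n >= min_n, , drop = FALSE]
  out <- out[order(out$roi_id, out$band), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    abort_normkit(sprintf("no parcel reaches min_n = %d subjects", min_n),
                  "normkit_empty_map")
  trace$n_dropped_low_n <- nrow(dropped)
  structure(out, class = c("normative_map", "data.frame"),
            config_hash = config_hash,
            subjects = sort(unique(rows$subject_id)),
            trace = trace)
}

#' Write / read a normative map (CSV + JSON provenance sidecar)
#'
#' @param map a `normative_map`.
#' @param path CSV path; provenance goes to `<path>.provenance.json`.
#' @return `path` / the map.
#' @export
write_normative_map <- function(map, path) {
  lm <- dk_label_map()
  df <- as.data.frame(map)
  df$roi_name <- lm$roi_name[match(df$roi_id, lm$label)]
  utils::write.csv(df[, c("roi_id", "roi_name", "band", "mean_log_rbp",
                          "sd_log_rbp", "n")], path, row.names = FALSE)
  write_json_file(list(config_hash = attr(map, "config_hash"),
                       subjects = attr(map, "subjects"),
                       trace = attr(map, "trace")),
                  paste0(path, ".provenance.json"))
  invisible(path)
}

#' @rdname write_normative_map
#' @export
read_normative_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prov <- read_json_file(paste0(path, ".provenance.json"))
  structure(df[, c("roi_id", "band", "mean_log_rbp", "sd_log_rbp", "n")],
            class = c("normative_map", "data.frame"),
            config_hash = prov$config_hash,
            subjects = prov$subjects, trace = prov$trace)
}

# Hash of every decision-point parameter that must match between the map
# and any subject scored against it.
metric_config_hash <- function(params, bands, welch = list(window_sec = 2,
                                                           overlap = 0.5)) {
  canon <- list(reference = params$reference, bandpass = params$bandpass,
                notch_base = params$notch_base,
                notch_width = params$notch_width,
                target_fs = params$target_fs,
                bands = as.data.frame(bands), welch = welch)
  md5_string(canonical_json(canon))
}
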