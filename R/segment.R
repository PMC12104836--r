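# Interictal segment records and their on-disk container.
#
# A segment is stored as a flat little-endian float64 binary file
# ("<stem>.dat", channel-major rows) next to a JSON sidecar ("<stem>.json")
# holding all metadata, so the round trip is bit-exact and diff-friendly.

#' Construct a segment record
#'
#' One fixed-length interictal icEEG excerpt plus its extraction metadata:
#' channel names, the subsets flagged unsuitable or spiking, start datetime,
#' duration, sampling frequency, wake status, subject/hospital identity and
#' segment number.
#'
#' @param data channels x samples numeric matrix.
#' @param channel_names character vector, one per data row.
#' @param fs sampling frequency (Hz).
#' @param start_datetime POSIXct (UTC) start of the segment.
#' @param duration seconds (defaults to `ncol(data) / fs`).
#' @param wake_status one of `"W"`, `"N1"`, `"N2"`, `"N3"`, `"R"`, `"NA"`.
#' @param subject_id,hospital,segment_number identity metadata.
#' @param unsuitable_channels,spiking_channels subsets of `channel_names`.
#' @param reference reference type, `"referential"` or `"bipolar"`.
#' @return object of class `segment_record`.
#' @export
segment_record <- function(data, channel_names, fs, start_datetime,
                           duration = ncol(data) / fs,
                           wake_status = "W", subject_id, hospital,
                           segment_number = 1L,
                           unsuitable_channels = character(),
                           spiking_channels = character(),
                           reference = "referential") {
  data <- as.matrix(data)
  assert_that(nrow(data) == length(channel_names),
              "data row count must equal number of channel names")
  assert_that(!anyDuplicated(channel_names), "duplicate channel names")
  assert_that(all(unsuitable_channels %in% channel_names),
              "unsuitable_channels must be a subset of channel_names")
  assert_that(all(spiking_channels %in% channel_names),
              "spiking_channels must be a subset of channel_names")
  assert_that(abs(duration * fs - ncol(data)) <= 1,
              "duration * fs must match sample count (within one sample)")
  assert_that(wake_status %in% c("W", "N1", "N2", "N3", "R", "NA"),
              "invalid wake_status")
  rownames(data) <- channel_names
  structure(list(
    data = data,
    channel_names = channel_names,
    unsuitable_channels = unsuitable_channels,
    spiking_channels = spiking_channels,
    fs = fs,
    start_datetime = start_datetime,
    duration = duration,
    wake_status = wake_status,
    subject_id = subject_id,
    hospital = hospital,
    segment_number = as.integer(segment_number),
    reference = reference
  ), class = "segment_record")
}

#' @export
print.segment_record <- function(x, ...) {
  cat(sprintf(
    "<segment_record> %s seg %d: %d ch x %.6g s @ %g Hz, state %s, start %s\n",
    x$subject_id, x$segment_number, nrow(x$data), x$duration, x$fs,
    x$wake_status, format_datetime(x$start_datetime)))
  if (length(x$unsuitable_channels))
    cat("  unsuitable:", paste(x$unsuitable_channels, collapse = ", "), "\n")
  if (length(x$spiking_channels))
    cat("  spiking:", paste(x$spiking_channels, collapse = ", "), "\n")
  invisible(x)
}

# Drop channels from a segment, preserving flag subsets.
segment_subset <- function(seg, keep_names) {
  assert_that(all(keep_names %in% seg$channel_names),
              "keep_names must be existing channels")
  seg$data <- seg$data[keep_names, , drop = FALSE]
  seg$channel_names <- keep_names
  seg$unsuitable_channels <- intersect(seg$unsuitable_channels, keep_names)
  seg$spiking_channels <- intersect(seg$spiking_channels, keep_names)
  seg
}

#' Write a segment record to its container files
#'
#' @param seg a `segment_record`.
#' @param stem output path stem; writes `<stem>.dat` + `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_segment <- function(seg, stem) {
  assert_that(inherits(seg, "segment_record"), "seg must be a segment_record")
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(stem, ".dat"), "wb")
  writeBin(as.vector(t(seg$data)), con, size = 8L, endian = "little")
  close(con)
  meta <- list(
    format = "normkit-segment-v1",
    channel_names = seg$channel_names,
    unsuitable_channels = seg$unsuitable_channels,
    spiking_channels = seg$spiking_channels,
    n_channels = nrow(seg$data),
    n_samples = ncol(seg$data),
    fs = seg$fs,
    start_datetime = format_datetime(seg$start_datetime),
    duration = seg$duration,
    wake_status = seg$wake_status,
    subject_id = seg$subject_id,
    hospital = seg$hospital,
    segment_number = seg$segment_number,
    reference = seg$reference
  )
  write_json_file(meta, paste0(stem, ".json"))
  invisible(stem)
}

#' Read a segment record from its container files
#'
#' @param stem path stem written by [write_segment()].
#' @return a `segment_record`.
#' @export
read_segment <- function(stem) {
  meta <- read_json_file(paste0(stem, ".json"))
  assert_that(identical(meta$format, "normkit-segment-v1"),
              "not a normkit segment container")
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(stem, ".dat"), "rb")
  vec <- readBin(con, "double", n = n, size = 8L, endian = "little")
  close(con)
  assert_that(length(vec) == n, "truncated segment data file")
  data <- matrix(vec, nrow = meta$n_channels, byrow = TRUE)
  segment_record(
    data = data,
    channel_names = as.character(meta$channel_names),
    unsuitable_channels = as.character(meta$unsuitable_channels %||% character()),
    spiking_channels = as.character(meta$spiking_channels %||% character()),
    fs = meta$fs,
    start_datetime = parse_datetime(meta$start_datetime),
    duration = meta$duration,
    wake_status = meta$wake_status,
    subject_id = meta$subject_id,
    hospital = meta$hospital,
    segment_number = meta$segment_number,
    reference = meta$reference
  )
}
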