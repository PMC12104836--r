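# Spatial processing: channel-to-parcel localisation and resection
# distances.

#' Nearest same-hemisphere grey-matter parcel
#'
#' Minimum world-space Euclidean distance from a point to the centres of
#' grey-matter voxels whose parcel hemisphere matches the channel's
#' hemisphere. Channels further than `max_dist` from grey matter are
#' unassigned (`roi_id = NA`). Ties are broken by smallest label id, then
#' lexicographic voxel index.
#'
#' @param xyz numeric length-3 world coordinates (mm).
#' @param parc a [parcellation_volume()].
#' @param hemisphere `"left"` or `"right"`.
#' @param max_dist assignment threshold in mm (default 5).
#' @return list with `roi_id` (label or NA) and `dist` (mm to nearest
#'   matching grey voxel).
#' @export
nearest_grey_roi <- function(xyz, parc, hemisphere, max_dist = 5) {
  assert_that(hemisphere %in% c("left", "right"),
              "hemisphere must be 'left' or 'right'")
  assert_that(max_dist > 0, "max_dist must be positive")
  gv <- grey_voxel_table(parc, hemisphere)
  if (!nrow(gv))
    abort_normkit(sprintf("parcellation has no grey-matter voxels in the %s hemisphere",
                          hemisphere), "normkit_no_grey")
  d2 <- (gv$x - xyz[1])^2 + (gv$y - xyz[2])^2 + (gv$z - xyz[3])^2
  dmin <- min(d2)
  # gv rows are pre-sorted by (label, i, j, k): first hit is the tie-break
  hit <- which(d2 <= dmin + 1e-9)[1L]
  dist <- sqrt(d2[hit])
  list(roi_id = if (dist > max_dist) NA_integer_ else gv$label[hit],
       dist = dist)
}

#' Minimum distance to a resection mask
#'
#' @param xyz numeric length-3 world coordinates (mm).
#' @param mask 3-D 0/1 array.
#' @param affine 4x4 voxel-to-world matrix of the mask volume.
#' @return minimum Euclidean distance (mm) to any mask-voxel centre.
#' @export
distance_to_mask <- function(xyz, mask, affine) {
  mv <- mask_voxel_coords(mask, affine)
  if (!nrow(mv)) abort_normkit("resection mask is empty", "normkit_empty_mask")
  sqrt(min((mv[, 1] - xyz[1])^2 + (mv[, 2] - xyz[2])^2 + (mv[, 3] - xyz[3])^2))
}

#' Build the per-channel localisation table
#'
#' One record per channel: nearest same-hemisphere grey parcel (with the
#' distance threshold), distance to the resection mask and the derived
#' resected flag when a mask is supplied, and pass-through pathology flags.
#' Flags that are not supplied stay absent (NA), not FALSE.
#'
#' @param coords data.frame with columns name, x, y, z, electrode_type,
#'   hemisphere.
#' @param parc a [parcellation_volume()].
#' @param mask optional list(data, affine) resection mask volume.
#' @param max_grey_dist grey-matter assignment threshold, mm (default 5).
#' @param resect_dist resected-channel threshold on mask distance, mm
#'   (default 5).
#' @param flags optional data.frame keyed by `name` with any of
#'   `is_resected`, `is_spiking`, `is_structurally_abnormal`,
#'   `is_within_soz` (clinical-report flags; an `is_resected` column here
#'   bypasses the mask computation for those channels).
#' @return data.frame with columns name, x, y, z, electrode_type,
#'   hemisphere, roi_id, roi_name, dist_to_grey, dist_to_mask, is_resected,
#'   is_spiking, is_structurally_abnormal, is_within_soz.
#' @export
build_channel_table <- function(coords, parc, mask = NULL,
                                max_grey_dist = 5, resect_dist = 5,
                                flags = NULL) {
  needed <- c("name", "x", "y", "z", "electrode_type", "hemisphere")
  assert_that(all(needed %in% names(coords)),
              sprintf("coords needs columns %s", paste(needed, collapse = ", ")))
  assert_that(!anyDuplicated(coords$name), "duplicate channel names")
  lm <- parc$label_map
  n <- nrow(coords)
  roi_id <- integer(n); dist_grey <- numeric(n)
  for (i in seq_len(n)) {
    hit <- nearest_grey_roi(c(coords$x[i], coords$y[i], coords$z[i]), parc,
                            coords$hemisphere[i], max_dist = max_grey_dist)
    roi_id[i] <- hit$roi_id
    dist_grey[i] <- hit$dist
  }
  out <- data.frame(
    name = coords$name, x = coords$x, y = coords$y, z = coords$z,
    electrode_type = coords$electrode_type, hemisphere = coords$hemisphere,
    roi_id = roi_id,
    roi_name = lm$roi_name[match(roi_id, lm$label)],
    dist_to_grey = dist_grey,
    dist_to_mask = NA_real_,
    is_resected = NA, is_spiking = NA,
    is_structurally_abnormal = NA, is_within_soz = NA,
    stringsAsFactors = FALSE)
  if (!is.null(mask)) {
    for (i in seq_len(n)) {
      out$dist_to_mask[i] <- distance_to_mask(
        c(coords$x[i], coords$y[i], coords$z[i]), mask$data, mask$affine)
    }
    out$is_resected <- out$dist_to_mask <= resect_dist
  }
  if (!is.null(flags)) {
    assert_that("name" %in% names(flags), "flags needs a name column")
    idx <- match(out$name, flags$name)
    for (fl in c("is_resected", "is_spiking", "is_structurally_abnormal",
                 "is_within_soz")) {
      if (fl %in% names(flags)) {
        v <- flags[[fl]][idx]
        out[[fl]] <- ifelse(is.na(idx), out[[fl]], as.logical(v))
      }
    }
  }
  out
}

#' Write / read a channel table as CSV
#'
#' @param tbl channel table from [build_channel_table()].
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_channel_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_channel_table
#' @export
read_channel_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(name = "character"))
  for (fl in c("is_resected", "is_spiking", "is_structurally_abnormal",
               "is_within_soz"))
    if (fl %in% names(tbl)) tbl[[fl]] <- as.logical(tbl[[fl]])
  tbl
}
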