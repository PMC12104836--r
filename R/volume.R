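# Labelled parcellation volumes and the toy atlas label lookup.

#' Built-in label lookup for the synthetic atlas
#'
#' A small subset of a Desikan-Killiany-style lookup used by the synthetic
#' volumes and examples. Subcortical ids (17/53 hippocampus, 18/54 amygdala)
#' and the white-matter ids (2/41) follow the standard FreeSurfer colour
#' lookup; cortical parcel ids follow the sequential ROI-tutorial numbering
#' (39 = lh-middle-temporal). Right-hemisphere / extra synthetic parcels are
#' numbered in the same style and are documented as synthetic.
#'
#' @return data.frame with columns `label`, `roi_name`, `hemisphere`,
#'   `tissue`.
#' @export
dk_label_map <- function() {
  data.frame(
    label = c(2L, 41L, 17L, 53L, 18L, 54L, 39L, 74L, 44L, 79L),
    roi_name = c("Left-Cerebral-White-Matter", "Right-Cerebral-White-Matter",
                 "Left-Hippocampus", "Right-Hippocampus",
                 "Left-Amygdala", "Right-Amygdala",
                 "lh-middle-temporal", "rh-middle-temporal",
                 "lh-superior-frontal", "rh-superior-frontal"),
    hemisphere = c("left", "right", "left", "right", "left", "right",
                   "left", "right", "left", "right"),
    tissue = c("white", "white", "grey", "grey", "grey", "grey",
               "grey", "grey", "grey", "grey"),
    stringsAsFactors = FALSE
  )
}

#' Construct a parcellation volume
#'
#' Container pairing a 3-D integer label array with its voxel-to-world affine
#' and a label lookup giving, for every non-zero label, the parcel name,
#' hemisphere and tissue class.
#'
#' @param labels 3-D integer array (0 = background).
#' @param affine 4x4 voxel-to-world (mm) matrix over 0-based voxel indices.
#' @param label_map data.frame with columns `label`, `roi_name`,
#'   `hemisphere` (`"left"`/`"right"`), `tissue` (`"grey"`/`"white"`/`"other"`).
#' @return object of class `parcellation_volume`.
#' @export
parcellation_volume <- function(labels, affine, label_map = dk_label_map()) {
  assert_that(length(dim(labels)) == 3L, "labels must be a 3-D array")
  assert_that(is.matrix(affine) && all(dim(affine) == c(4, 4)),
              "affine must be 4x4")
  assert_that(abs(det(affine[1:3, 1:3])) > 1e-12, "affine must be invertible")
  needed <- c("label", "roi_name", "hemisphere", "tissue")
  assert_that(all(needed %in% names(label_map)),
              "label_map needs columns label, roi_name, hemisphere, tissue")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  missing <- setdiff(present, label_map$label)
  assert_that(length(missing) == 0L,
              sprintf("labels present in volume but absent from label_map: %s",
                      paste(missing, collapse = ", ")))
  structure(list(labels = labels, affine = affine,
                 label_map = label_map[, needed]),
            class = "parcellation_volume")
}

#' @export
print.parcellation_volume <- function(x, ...) {
  cat(sprintf("<parcellation_volume> %s voxels, %d labelled parcels\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$label_map$label %in% unique(as.vector(x$labels)))))
  invisible(x)
}

# World coordinates (mm) of voxel centres for 0-based voxel index matrix ijk.
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(t(ijk), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

# 0-based voxel indices (i, j, k) of every voxel whose label passes `keep`.
voxel_indices_where <- function(labels, keep) {
  idx <- which(keep)
  if (!length(idx)) return(matrix(numeric(), ncol = 3))
  d <- dim(labels)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(i = i, j = j, k = k)
}

# Cache of grey-voxel world coordinates per hemisphere, in deterministic
# tie-break order: label id, then i, then j, then k.
grey_voxel_table <- function(parc, hemisphere) {
  lm <- parc$label_map
  grey_labels <- lm$label[lm$tissue == "grey" & lm$hemisphere == hemisphere]
  keep <- array(parc$labels %in% grey_labels, dim = dim(parc$labels))
  ijk <- voxel_indices_where(parc$labels, keep)
  if (!nrow(ijk)) {
    return(data.frame(label = integer(), i = numeric(), j = numeric(),
                      k = numeric(), x = numeric(), y = numeric(),
                      z = numeric()))
  }
  lab <- parc$labels[keep]
  ord <- order(lab, ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- ijk[ord, , drop = FALSE]
  lab <- lab[ord]
  xyz <- voxel_to_world(ijk, parc$affine)
  data.frame(label = lab, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# World coordinates of non-zero voxels of a binary mask volume.
mask_voxel_coords <- function(mask, affine) {
  keep <- array(mask != 0, dim = dim(mask))
  ijk <- voxel_indices_where(mask, keep)
  if (!nrow(ijk)) return(matrix(numeric(), ncol = 3))
  voxel_to_world(ijk, affine)
}
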