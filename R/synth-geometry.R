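# Synthetic toy geometry: labelled volume, electrode coordinates, masks.

SYNTH_ELECTRODES <- data.frame(
  roi = c(17L, 18L, 39L, 44L, 53L, 54L, 74L, 79L),
  electrode = c("LHIP", "LAMY", "LMT", "LSF", "RHIP", "RAMY", "RMT", "RSF"),
  stringsAsFactors = FALSE
)

# Block origins (0-based voxel corners) of the 10-voxel grey cubes.
synth_block_origins <- function() {
  data.frame(
    roi = c(17L, 18L, 39L, 44L, 53L, 54L, 74L, 79L),
    i0 = c(6L, 6L, 6L, 6L, 40L, 40L, 40L, 40L),
    j0 = c(6L, 28L, 6L, 28L, 6L, 28L, 6L, 28L),
    k0 = c(6L, 6L, 24L, 24L, 6L, 6L, 24L, 24L)
  )
}

synth_volume_dims <- function() c(56L, 44L, 40L)

# voxel -> world: 1 mm isotropic, centred so the left hemisphere has x < 0
synth_affine <- function() {
  a <- diag(4)
  a[1:3, 4] <- c(-28, -22, -20)
  a
}

#' Generate toy geometry for a synthetic subject
#'
#' Builds the shared 1 mm isotropic label volume (eight 10 mm grey cubes,
#' four per hemisphere, inside white-matter slabs), places the subject's
#' depth-electrode contacts at jittered voxel centres inside designated grey
#' cubes (so the true nearest same-hemisphere grey parcel is known by
#' construction), and rasterises a resection mask over any ROIs designated
#' resected.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for the coordinate jitter.
#' @param resected_rois integer parcel ids covered by the resection mask.
#' @return list with `parc` (a [parcellation_volume()]), `channels`
#'   (data.frame name/x/y/z/electrode_type/hemisphere/true_roi) and `mask`
#'   (3-D 0/1 array, or NULL when `resected_rois` is empty).
#' @export
generate_geometry <- function(config, seed = config$seed,
                              resected_rois = integer()) {
  dims <- synth_volume_dims()
  blocks <- synth_block_origins()
  labels <- array(0L, dim = dims)
  # white matter slabs flanking the midline
  labels[19:28, 4:40, 4:36] <- 2L
  labels[29:38, 4:40, 4:36] <- 41L
  for (b in seq_len(nrow(blocks))) {
    i <- blocks$i0[b]; j <- blocks$j0[b]; k <- blocks$k0[b]
    labels[(i + 1):(i + 10), (j + 1):(j + 10), (k + 1):(k + 10)] <- blocks$roi[b]
  }
  parc <- parcellation_volume(labels, synth_affine())

  n_ch <- config$n_channels
  assert_that(n_ch <= 32, "toy geometry supports at most 32 contacts (4 per track)")
  # round-robin over the eight electrode tracks
  track <- rep(seq_len(nrow(SYNTH_ELECTRODES)), length.out = n_ch)
  contact_no <- stats::ave(track, track, FUN = seq_along)
  lm <- parc$label_map
  coords <- with_seed(derive_seed(seed, "geometry"), {
    out <- vector("list", n_ch)
    for (c_idx in seq_len(n_ch)) {
      roi <- SYNTH_ELECTRODES$roi[track[c_idx]]
      b <- blocks[blocks$roi == roi, ]
      # interior voxel centres spaced 2 voxels along j, jitter < 0.5 mm
      ijk <- c(b$i0 + 4, b$j0 + 1 + 2 * contact_no[c_idx], b$k0 + 5)
      xyz <- voxel_to_world(matrix(ijk, nrow = 1), parc$affine) +
        stats::runif(3, -0.3, 0.3)
      out[[c_idx]] <- data.frame(
        name = paste0(SYNTH_ELECTRODES$electrode[track[c_idx]], contact_no[c_idx]),
        x = xyz[1], y = xyz[2], z = xyz[3],
        electrode_type = "depth",
        hemisphere = lm$hemisphere[match(roi, lm$label)],
        true_roi = roi,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  mask <- NULL
  if (length(resected_rois)) {
    mask <- array(0L, dim = dims)
    mask[labels %in% resected_rois] <- 1L
  }
  list(parc = parc, channels = coords, mask = mask)
}
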