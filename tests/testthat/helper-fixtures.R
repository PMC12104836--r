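# Shared fixtures and independent oracles, all built in code.

pd <- normkit:::parse_datetime

# Tiny deterministic parcellation: one grey cube per hemisphere plus white.
tiny_parcellation <- function() {
  labels <- array(0L, dim = c(20L, 16L, 12L))
  labels[3:6, 5:8, 4:7] <- 17L    # left hippocampus cube
  labels[14:17, 5:8, 4:7] <- 53L  # right hippocampus cube
  labels[8:9, 3:14, 2:10] <- 2L   # left white
  labels[11:12, 3:14, 2:10] <- 41L
  aff <- diag(4); aff[1:3, 4] <- c(-10, -8, -6)
  parcellation_volume(labels, aff)
}

# Random toy parcellation with grey labels in both hemispheres.
random_parcellation <- function(seed) {
  set.seed(seed)
  d <- c(sample(10:14, 1), sample(8:12, 1), sample(8:12, 1))
  labels <- array(0L, dim = d)
  lm <- dk_label_map()
  left_grey <- lm$label[lm$tissue == "grey" & lm$hemisphere == "left"]
  right_grey <- lm$label[lm$tissue == "grey" & lm$hemisphere == "right"]
  half <- d[1] %/% 2
  n_vox <- prod(d)
  for (lab in sample(left_grey, 2)) {
    idx <- cbind(sample(1:half, 15, TRUE), sample(1:d[2], 15, TRUE),
                 sample(1:d[3], 15, TRUE))
    labels[idx] <- lab
  }
  for (lab in sample(right_grey, 2)) {
    idx <- cbind(sample((half + 1):d[1], 15, TRUE), sample(1:d[2], 15, TRUE),
                 sample(1:d[3], 15, TRUE))
    labels[idx] <- lab
  }
  aff <- diag(4); aff[1:3, 4] <- -c(half, d[2] / 2, d[3] / 2)
  parcellation_volume(labels, aff)
}

# Independent nearest-grey oracle: plain loop over every voxel, applying
# the same-hemisphere constraint, the max_dist rule and the documented
# tie-breaks (label id, then i, then j, then k).
oracle_nearest_grey <- function(xyz, parc, hemisphere, max_dist = 5) {
  lm <- parc$label_map
  ok_labels <- lm$label[lm$tissue == "grey" & lm$hemisphere == hemisphere]
  lin <- which(array(parc$labels %in% ok_labels, dim = dim(parc$labels)))
  if (!length(lin)) stop("oracle: no matching grey voxels")
  ijk <- arrayInd(lin, dim(parc$labels)) - 1L
  lab <- parc$labels[lin]
  d2 <- numeric(length(lin))
  for (v in seq_along(lin)) {
    w <- parc$affine %*% c(ijk[v, ], 1)
    d2[v] <- sum((w[1:3] - xyz)^2)
  }
  dmin <- min(d2)
  tied <- which(d2 <= dmin + 1e-9)
  # tie-break: smallest label, then lexicographic (i, j, k)
  o <- tied[order(lab[tied], ijk[tied, 1], ijk[tied, 2], ijk[tied, 3])][1]
  dist <- sqrt(d2[o])
  list(roi_id = if (dist > max_dist) NA_integer_ else lab[o], dist = dist)
}

# Parcellation covering the printed hippocampal electrode coordinates:
# label 17 around world x in [-42, -25], label 39 in [-78, -43].
example_parcellation <- function() {
  labels <- array(0L, dim = c(60L, 20L, 22L))
  aff <- diag(4); aff[1:3, 4] <- c(-80, -25, -15)
  # voxel i maps to world x = i - 1 - 80
  labels[39:56, 6:16, 3:19] <- 17L
  labels[3:38, 6:16, 3:19] <- 39L
  parcellation_volume(labels, aff)
}

table1_fixture <- function() {
  utils::read.csv(system.file("extdata", "example_channel_table.csv",
                              package = "normkit"), stringsAsFactors = FALSE)
}

table2_fixture <- function() {
  f <- utils::read.csv(system.file("extdata", "example_channel_flags.csv",
                                   package = "normkit"),
                       stringsAsFactors = FALSE)
  for (col in names(f)[-1]) f[[col]] <- as.logical(f[[col]])
  f
}

make_segment <- function(data, fs = 200, names = NULL, ...) {
  if (is.null(names)) names <- paste0("ch", seq_len(nrow(data)))
  segment_record(data, names, fs, pd("2024-03-04T09:00:00"),
                 subject_id = "SYNH_001", hospital = "SYNH", ...)
}

# Pairwise-enumeration AUC oracle.
oracle_auc <- function(scores_pos, scores_neg) {
  wins <- 0
  for (a in scores_pos) for (b in scores_neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(scores_pos) * length(scores_neg))
}

# Leave-one-out z oracle for one vector.
oracle_loo_z <- function(x) {
  vapply(seq_along(x), function(i) {
    rest <- x[-i]
    s <- stats::sd(rest)
    if (!is.finite(s) || s == 0) return(NA_real_)
    (x[i] - mean(rest)) / s
  }, numeric(1))
}

default_policy <- function(...) selection_policy(...)

# Per-second constraint checker for an emitted placement.
oracle_check_placement <- function(timeline, policy, start) {
  len <- policy$segment_length
  secs <- seq(floor(start), ceiling(start + len) - 1)
  st <- timeline$states
  state_of <- function(s) {
    hit <- which(st$start <= s & st$end > s)
    if (length(hit)) st$state[hit[1]] else NA_character_
  }
  ok_state <- all(vapply(secs, function(s)
    identical(state_of(s), policy$state), logical(1)))
  ok_skip <- start >= timeline$implant_time + policy$post_implant_skip * 3600
  ok_buffer <- TRUE
  if (nrow(timeline$seizures)) {
    for (i in seq_len(nrow(timeline$seizures))) {
      b <- policy$seizure_buffer[[timeline$seizures$type[i]]] * 3600
      lo <- timeline$seizures$onset[i] - b
      hi <- timeline$seizures$onset[i] + timeline$seizures$duration[i] + b
      if (start < hi && start + len > lo) ok_buffer <- FALSE
    }
  }
  f <- timeline$files
  cover <- which(f$start <= start & f$end >= start + len)
  ok_fs <- length(cover) > 0 && all(f$fs[cover] >= policy$min_fs)
  c(state = ok_state, skip = ok_skip, buffer = ok_buffer, fs = ok_fs)
}
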