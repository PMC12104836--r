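# Abnormality mapping: regional z-scores against the normative map,
# max-|z| abnormality, resected/spared labelling and the D_RS statistic.

#' Regional z-scores against a normative map
#'
#' z = (x - mean) / SD per parcel and band. The subject's metric must have
#' been computed under the same configuration as the map: when both carry a
#' config hash they are compared and a mismatch is an error. Parcels absent
#' from the map are left unscored and listed; map cells with zero SD are
#' rejected with a diagnostic.
#'
#' @param subject_rows data.frame roi_id / band / log_rbp for one subject
#'   (optionally with a `config_hash` attribute).
#' @param map a `normative_map`.
#' @return data.frame roi_id / band / log_rbp / z, with unscored parcel ids
#'   in `attr(, "unscored_rois")`.
#' @export
zscores <- function(subject_rows, map) {
  sub_hash <- attr(subject_rows, "config_hash")
  map_hash <- attr(map, "config_hash")
  if (!is.null(sub_hash) && !is.null(map_hash) &&
      !is.na(sub_hash) && !is.na(map_hash) && !identical(sub_hash, map_hash))
    abort_normkit("metric configuration hash differs from the normative map's",
                  "normkit_config_mismatch")
  m <- merge(subject_rows, as.data.frame(map), by = c("roi_id", "band"),
             all.x = TRUE)
  unscored <- sort(unique(m$roi_id[is.na(m$mean_log_rbp)]))
  m <- m[!is.na(m$mean_log_rbp), , drop = FALSE]
  bad <- m$sd_log_rbp == 0
  if (any(bad))
    abort_normkit(sprintf("zero normative SD for %s",
                          paste(unique(paste0(m$roi_id[bad], ":", m$band[bad])),
                                collapse = ", ")), "normkit_zero_sd")
  m$z <- (m$log_rbp - m$mean_log_rbp) / m$sd_log_rbp
  out <- m[order(m$roi_id, m$band), c("roi_id", "band", "log_rbp", "z")]
  rownames(out) <- NULL
  attr(out, "unscored_rois") <- unscored
  out
}

#' Regional abnormality: maximum absolute z across bands
#'
#' @param z_table output of [zscores()].
#' @return data.frame roi_id / abnormality / band (the band attaining the
#'   maximum).
#' @export
regional_abnormality <- function(z_table) {
  assert_that(nrow(z_table) > 0, "empty z table")
  out <- do.call(rbind, lapply(split(z_table, z_table$roi_id), function(g) {
    i <- which.max(abs(g$z))
    data.frame(roi_id = g$roi_id[1], abnormality = abs(g$z[i]),
               band = g$band[i], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$roi_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label parcels as resected or spared
#'
#' A parcel is resected when strictly more than `threshold` of its channels
#' were resected; parcels with no channels are unlabelled (absent).
#'
#' @param channel_table data.frame with `roi_id` and `is_resected`.
#' @param threshold resected-channel proportion (default 0.25, strict `>`).
#' @return data.frame roi_id / n_channels / n_resected / label.
#' @export
label_resected_regions <- function(channel_table, threshold = 0.25) {
  tbl <- channel_table[!is.na(channel_table$roi_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tbl, tbl$roi_id), function(g) {
    res <- sum(!is.na(g$is_resected) & g$is_resected)
    data.frame(roi_id = g$roi_id[1], n_channels = nrow(g), n_resected = res,
               label = if (res / nrow(g) > threshold) "resected" else "spared",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$roi_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' D_RS: distinguishability of resected vs spared parcels
#'
#' Mann-Whitney AUC computed by the closed-form rank method with exact tie
#' handling: the probability that a resected parcel scores above a spared
#' one (ties count half). 1 means resected parcels are uniformly more
#' abnormal; `orientation = "spared"` flips the convention.
#'
#' @param abnormality named numeric vector (or [regional_abnormality()]
#'   data.frame) of parcel scores.
#' @param labels named character vector (or [label_resected_regions()]
#'   data.frame) of `"resected"`/`"spared"` labels.
#' @param orientation which class counts as positive (default
#'   `"resected"`).
#' @return D_RS in `[0, 1]`.
#' @export
drs <- function(abnormality, labels, orientation = c("resected", "spared")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(abnormality))
    abnormality <- stats::setNames(abnormality$abnormality,
                                   abnormality$roi_id)
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$roi_id)
  common <- intersect(names(abnormality), names(labels))
  scores <- abnormality[common]
  lab <- labels[common]
  pos <- lab == orientation
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    abort_normkit(sprintf("D_RS undefined: no scored %s parcel",
                          if (n_pos == 0) orientation
                          else setdiff(c("resected", "spared"), orientation)),
                  "normkit_drs_undefined")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score one subject against a normative map
#'
#' Convenience wrapper for the full regional abnormality result: z-scores,
#' max-|z| abnormality, resected/spared labels and D_RS (when both classes
#' are present).
#'
#' @param subject_rows data.frame roi_id / band / log_rbp.
#' @param map a `normative_map`.
#' @param channel_table channel table with resected flags (optional).
#' @param resect_threshold region-resected proportion threshold.
#' @return list with `z`, `abnormality`, `labels` (or NULL) and `d_rs` (or
#'   NA when undefined).
#' @export
score_subject <- function(subject_rows, map, channel_table = NULL,
                          resect_threshold = 0.25) {
  z <- zscores(subject_rows, map)
  ab <- regional_abnormality(z)
  labels <- NULL
  d <- NA_real_
  if (!is.null(channel_table)) {
    labels <- label_resected_regions(channel_table,
                                     threshold = resect_threshold)
    labs <- labels[labels$roi_id %in% ab$roi_id, , drop = FALSE]
    if (length(unique(labs$label)) == 2) d <- drs(ab, labs)
  }
  list(z = z, abnormality = ab, labels = labels, d_rs = d)
}
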