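# Frequency band schemes for relative band power.

#' Construct a band scheme
#'
#' An ordered set of contiguous, non-overlapping half-open frequency bands
#' `[low, high)` whose union is the analysis range. The default is the
#' five-band clinical scheme used throughout the package: delta `[1, 4)`,
#' theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30)`, gamma `[30, 47.5)` Hz
#' (gamma is capped below typical 50/60 Hz mains interference).
#'
#' @param edges named numeric vector of band lower edges plus a final
#'   unnamed/`.high` upper edge, or NULL for the default scheme.
#' @return object of class `band_scheme`: data.frame with `band`, `low`,
#'   `high`.
#' @export
band_scheme <- function(edges = NULL) {
  if (is.null(edges)) {
    df <- data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
                     low = c(1, 4, 8, 13, 30),
                     high = c(4, 8, 13, 30, 47.5),
                     stringsAsFactors = FALSE)
  } else {
    assert_that(!is.null(names(edges)) && sum(names(edges) == "") <= 1,
                "edges must be a named vector of lower edges + final upper edge")
    n <- length(edges) - 1L
    df <- data.frame(band = names(edges)[seq_len(n)],
                     low = unname(edges[seq_len(n)]),
                     high = unname(edges[-1L]),
                     stringsAsFactors = FALSE)
  }
  assert_that(all(df$high > df$low), "band edges must be increasing")
  if (nrow(df) > 1) {
    assert_that(all(abs(df$low[-1] - df$high[-nrow(df)]) < 1e-12),
                "bands must be contiguous")
  }
  structure(df, class = c("band_scheme", "data.frame"))
}

analysis_range <- function(bands) c(min(bands$low), max(bands$high))

# Map frequency-bin centres to band names ("" outside analysis range).
# Bins are assigned by the half-open [low, high) rule, so every in-range bin
# belongs to exactly one band and band powers sum exactly to the total.
assign_bins <- function(freq, bands) {
  idx <- findInterval(freq, c(bands$low, bands$high[nrow(bands)]),
                      rightmost.closed = FALSE, left.open = FALSE)
  out <- rep("", length(freq))
  in_range <- idx >= 1 & idx <= nrow(bands) & freq < bands$high[nrow(bands)]
  out[in_range] <- bands$band[idx[in_range]]
  out
}
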