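# Synthetic multichannel icEEG: 1/f background, band-limited oscillations,
# line noise, artifact and spiking channels.

# Folded two-sided frequency axis for an n-point FFT.
folded_freq <- function(n, fs) {
  f <- (seq_len(n) - 1L) * fs / n
  pmin(f, fs - f)
}

# Normalised power shapes (sum to 1 over the two-sided bins, zero where the
# component has no support).
shape_pink <- function(f, alpha = 2, f_lo = 0.5) {
  s <- ifelse(f < f_lo, 0, f^(-alpha))
  s / sum(s)
}

shape_band <- function(f, low, high) {
  s <- as.numeric(f >= low & f < high)
  if (sum(s) == 0) return(s)
  s / sum(s)
}

# Gaussian process with a prescribed power spectrum: one white-noise FFT
# shaped by sqrt(n * p(f)), where p sums to 1, gives a unit-variance signal.
spectrum_noise <- function(n, p) {
  W <- stats::fft(stats::rnorm(n))
  Re(stats::fft(W * sqrt(n * p), inverse = TRUE)) / n
}

# 1/f^(alpha) power background noise, unit variance (used for artifacts).
pink_background <- function(n, fs, alpha = 2, f_lo = 0.5) {
  y <- spectrum_noise(n, shape_pink(folded_freq(n, fs), alpha, f_lo))
  y / stats::sd(y)
}

# ~70 ms biphasic interictal-spike kernel (difference of Gaussians), unit peak.
spike_kernel <- function(fs) {
  t <- seq(-0.035, 0.035, by = 1 / fs)
  k <- exp(-((t + 0.008) / 0.006)^2) - 0.6 * exp(-((t - 0.012) / 0.012)^2)
  k / max(abs(k))
}

#' Generate a synthetic multichannel signal
#'
#' Each clean channel is 1/f background plus band-limited oscillations whose
#' variances follow the channel's relative band-power profile, plus a
#' narrow mains peak. Channels marked `artifact` get large-amplitude
#' low-frequency non-physiological noise; channels marked `spiking` get the
#' clean signal with superimposed ~70 ms biphasic transients (0.5-2/min).
#'
#' @param profiles channels x bands matrix of relative oscillatory power
#'   (rows sum to ~1), or a single profile vector recycled over channels.
#' @param duration seconds.
#' @param fs sampling frequency, Hz; must exceed `2 * line_noise_hz`.
#' @param line_noise_hz mains frequency (0 disables the mains component).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param channel_kind character vector per channel: `"clean"`,
#'   `"artifact"` or `"spiking"`.
#' @param oscillation_fraction fraction of clean-channel variance in the
#'   oscillations.
#' @param line_fraction fraction of clean-channel variance at the mains peak.
#' @param alpha 1/f exponent of the background power spectrum.
#' @param bands a [band_scheme()] giving the profile columns.
#' @param amplitude overall RMS scale, arbitrary units (~uV).
#' @return channels x samples numeric matrix with channel kind in
#'   `attr(, "channel_kind")`.
#' @export
generate_signal <- function(profiles, duration, fs, line_noise_hz = 60,
                            seed = 1L, channel_kind = NULL,
                            oscillation_fraction = 0.85,
                            line_fraction = 0.03, alpha = 2,
                            bands = band_scheme(), amplitude = 50) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  n_ch <- nrow(profiles)
  assert_that(ncol(profiles) == nrow(bands),
              "profiles must have one column per band")
  if (is.null(channel_kind)) channel_kind <- rep("clean", n_ch)
  assert_that(length(channel_kind) == n_ch,
              "channel_kind must have one entry per channel")
  if (line_noise_hz > 0)
    assert_that(fs > 2 * line_noise_hz,
                "sampling rate too low to represent the mains peak")
  n <- round(duration * fs)
  nyq <- fs / 2
  assert_that(n >= 2 * round(2 * fs), "duration must cover two Welch windows")

  f <- folded_freq(n, fs)
  pink <- shape_pink(f, alpha = alpha)
  band_shapes <- lapply(seq_len(nrow(bands)), function(b)
    shape_band(f, bands$low[b], min(bands$high[b], nyq * 0.95)))

  with_seed(seed, {
    out <- matrix(0, nrow = n_ch, ncol = n)
    tgrid <- (seq_len(n) - 1L) / fs
    for (ch in seq_len(n_ch)) {
      p <- profiles[ch, ] / sum(profiles[ch, ])
      bg_var <- 1 - oscillation_fraction - line_fraction
      # one spectral draw per channel: background + oscillations add in power
      ptot <- bg_var * pink
      for (b in seq_len(nrow(bands)))
        if (p[b] > 0) ptot <- ptot + oscillation_fraction * p[b] * band_shapes[[b]]
      sig <- spectrum_noise(n, ptot)
      if (line_noise_hz > 0 && line_fraction > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        sig <- sig + sqrt(2 * line_fraction) *
          sin(2 * pi * line_noise_hz * tgrid + phase)
      }
      gain <- amplitude * 10^stats::rnorm(1, 0, 0.02)
      if (channel_kind[ch] == "artifact") {
        # streaky large-amplitude non-physiological noise
        drift <- pink_background(n, fs, alpha = 4, f_lo = 0.1)
        steps <- cumsum(stats::rnorm(n, 0, 1)); steps <- steps / stats::sd(steps)
        sig <- 30 * (0.7 * drift + 0.3 * steps)
      } else if (channel_kind[ch] == "spiking") {
        k <- spike_kernel(fs)
        rate <- stats::runif(1, 0.5, 2) / 60
        n_spk <- stats::rpois(1, rate * duration)
        if (n_spk > 0) {
          pos <- sort(sample.int(n - length(k), n_spk))
          for (s0 in pos) {
            idx <- s0:(s0 + length(k) - 1L)
            sig[idx] <- sig[idx] + 4 * k
          }
        }
      }
      out[ch, ] <- gain * sig
    }
    attr(out, "channel_kind") <- channel_kind
    out
  })
}
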