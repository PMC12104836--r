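# Spectral estimation and zero-phase frequency-domain filtering.
#
# Filtering is done by direct FFT masking with raised-cosine (half-Hann)
# transition edges rather than IIR designs: the mask is exactly zero-phase,
# numerically exact at this scale, and needs no filter-design dependency.

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hamming windows, mean detrend per
#' window, one-sided density scaling.
#'
#' @param x numeric vector or channels-x-samples matrix.
#' @param fs sampling frequency (Hz).
#' @param window_sec window length in seconds (default 2 s, giving 0.5 Hz
#'   resolution).
#' @param overlap fractional overlap between windows (default 0.5).
#' @return list with `freq` (Hz) and `psd` (channels x frequencies matrix,
#'   power per Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  nwin <- round(window_sec * fs)
  assert_that(nwin >= 8, "Welch window too short")
  assert_that(n >= 2 * nwin, "signal shorter than two Welch windows")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nwin) - 1L) / (nwin - 1L))
  u <- sum(win^2)
  nfreq <- nwin %/% 2L + 1L
  psd <- matrix(0, nrow = nrow(x), ncol = nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nwin - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, win, `*`)
    ft <- t(apply(seg, 1L, stats::fft))
    if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
    p <- Mod(ft[, seq_len(nfreq), drop = FALSE])^2
    psd <- psd + p
  }
  psd <- psd / (length(starts) * fs * u)
  # one-sided: double all bins except DC (and Nyquist when nwin even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  list(freq = (seq_len(nfreq) - 1L) * fs / nwin, psd = psd)
}

# Raised-cosine frequency mask over the two-sided FFT frequency axis.
# Passband [low, high] with half-Hann transitions of width `trans` Hz.
fft_mask <- function(n, fs, low = NULL, high = NULL, trans = 0.5) {
  f <- abs((seq_len(n) - 1L) * fs / n)
  f <- pmin(f, fs - f) # two-sided -> folded frequency
  m <- rep(1, n)
  if (!is.null(low) && low > 0) {
    lo0 <- max(0, low - trans)
    ramp <- (f - lo0) / (low - lo0)
    m <- m * ifelse(f >= low, 1, ifelse(f <= lo0, 0, 0.5 - 0.5 * cos(pi * ramp)))
  }
  if (!is.null(high)) {
    hi1 <- high + trans
    ramp <- (hi1 - f) / (hi1 - high)
    m <- m * ifelse(f <= high, 1, ifelse(f >= hi1, 0, 0.5 - 0.5 * cos(pi * ramp)))
  }
  m
}

# Zero-phase band-pass via FFT masking; x is channels x samples.
fft_bandpass <- function(x, fs, low, high, trans = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  m <- fft_mask(n, fs, low = low, high = high, trans = trans)
  t(apply(x, 1L, function(ch) Re(stats::fft(stats::fft(ch) * m, inverse = TRUE)) / n))
}

# Zero-phase notch at `base` Hz and its harmonics up to `max_freq`;
# each notch removes [f0 - width/2, f0 + width/2].
fft_notch <- function(x, fs, base, width = 2, max_freq = fs / 2, trans = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  f <- abs((seq_len(n) - 1L) * fs / n)
  f <- pmin(f, fs - f)
  m <- rep(1, n)
  limit <- min(max_freq, fs / 2)
  harmonics <- if (base > limit) numeric() else seq(base, limit, by = base)
  for (f0 in harmonics) {
    lo <- f0 - width / 2; hi <- f0 + width / 2
    stopb <- f >= lo & f <= hi
    m[stopb] <- 0
    up <- f > hi & f < hi + trans
    m[up] <- pmin(m[up], 0.5 - 0.5 * cos(pi * (f[up] - hi) / trans))
    dn <- f < lo & f > lo - trans
    m[dn] <- pmin(m[dn], 0.5 - 0.5 * cos(pi * (lo - f[dn]) / trans))
  }
  t(apply(x, 1L, function(ch) Re(stats::fft(stats::fft(ch) * m, inverse = TRUE)) / n))
}

# Fourier-method resampling (as in the classic FFT resample): band-limited
# interpolation to n_out = round(n * target_fs / fs) samples.
fft_resample <- function(x, fs, target_fs) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (target_fs == fs) return(x)
  n <- ncol(x)
  n_out <- as.integer(round(n * target_fs / fs))
  resample_one <- function(ch) {
    X <- stats::fft(ch)
    Y <- complex(length.out = n_out)
    nh <- min(n, n_out)
    half <- nh %/% 2L
    Y[1] <- X[1]
    if (nh %% 2L == 1L) {
      if (half >= 1L) {
        Y[2:(half + 1L)] <- X[2:(half + 1L)]
        Y[(n_out - half + 1L):n_out] <- X[(n - half + 1L):n]
      }
    } else {
      if (half >= 2L) {
        Y[2:half] <- X[2:half]
        Y[(n_out - half + 2L):n_out] <- X[(n - half + 2L):n]
      }
      if (n_out < n) {
        # fold the old +/-half bins into the new Nyquist bin
        Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
      } else {
        # split the old Nyquist bin symmetrically
        Y[half + 1L] <- X[half + 1L] / 2
        Y[n_out - half + 1L] <- X[half + 1L] / 2
      }
    }
    Re(stats::fft(Y, inverse = TRUE)) / n
  }
  out <- t(apply(x, 1L, resample_one))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1L)
  out
}
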