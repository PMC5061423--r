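# FFT-based spectral primitives shared by the HRV, EEG asymmetry,
# time-frequency and classification modules.

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# One-sided periodogram with optional taper and zero-padding.
# Scaling is power spectral density (units^2/Hz): integrating over frequency
# recovers the tapered signal's mean square (Parseval).
periodogram <- function(x, fs, taper = NULL, nfft = NULL, demean = TRUE) {
  n <- length(x)
  if (demean) x <- x - mean(x)
  if (!is.null(taper)) {
    u <- sum(taper^2) / n            # taper power-normalization factor
    x <- x * taper
  } else u <- 1
  if (is.null(nfft)) nfft <- n
  if (nfft > n) x <- c(x, numeric(nfft - n))
  X <- stats::fft(x)
  half <- seq_len(floor(nfft / 2) + 1L)
  p <- Mod(X[half])^2 / (fs * n * u)
  p[-1L] <- p[-1L] * 2
  if (nfft %% 2L == 0L) p[length(p)] <- p[length(p)] / 2
  list(freq = (half - 1L) * fs / nfft, psd = p)
}

# Welch PSD: n_segments overlapping Hamming-tapered segments, averaged.
welch_psd <- function(x, fs, n_segments = 2L, overlap = 0.5, nfft = NULL) {
  n <- length(x)
  L <- floor(n / (1 + (n_segments - 1L) * (1 - overlap)))
  if (L < 8L) stop("signal too short for Welch segmentation")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, by = step, length.out = n_segments)
  starts <- starts[starts + L - 1L <= n]
  w <- hamming_window(L)
  if (is.null(nfft)) nfft <- max(next_pow2(4L * L), L)
  acc <- NULL
  for (s in starts) {
    pg <- periodogram(x[s:(s + L - 1L)], fs, taper = w, nfft = nfft)
    acc <- if (is.null(acc)) pg$psd else acc + pg$psd
  }
  list(freq = pg$freq, psd = acc / length(starts))
}

# Integrate PSD over a half-open frequency band [lo, hi).
band_power <- function(freq, psd, band) {
  df <- freq[2L] - freq[1L]
  sel <- freq >= band[1L] & freq < band[2L]
  sum(psd[sel]) * df
}

# Band power of a raw segment via a single rectangular-taper periodogram;
# used for alpha-ratio features and hemisphere asymmetry.
segment_band_power <- function(x, fs, band, nfft = NULL) {
  pg <- periodogram(x, fs, taper = NULL, nfft = nfft)
  band_power(pg$freq, pg$psd, band)
}
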