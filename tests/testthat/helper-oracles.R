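# Independent oracles used across the suite: direct-DFT band power (no fft
# shortcuts), a greedy schedule matcher for event F1, and small builders.

# Direct DFT band power: explicit correlation with complex exponentials at
# the analysis frequencies. PSD scaling matches biostress:::periodogram
# (one-sided, units^2/Hz) so band powers are directly comparable.
oracle_band_power <- function(x, fs, band, taper = NULL, nfft = NULL) {
  n <- length(x)
  x <- x - mean(x)
  if (!is.null(taper)) {
    u <- sum(taper^2) / n
    x <- x * taper
  } else u <- 1
  if (is.null(nfft)) nfft <- n
  freqs <- (0:(floor(nfft / 2))) * fs / nfft
  sel <- which(freqs >= band[1L] & freqs < band[2L])
  df <- fs / nfft
  tt <- seq_len(n) - 1L
  p <- vapply(sel, function(k) {
    f <- freqs[k]
    re <- sum(x * cos(2 * pi * f * tt / fs))
    im <- sum(x * sin(2 * pi * f * tt / fs))
    scale <- if (k == 1L || (nfft %% 2L == 0L && k == length(freqs))) 1 else 2
    scale * (re^2 + im^2) / (fs * n * u)
  }, numeric(1))
  sum(p) * df
}

# Greedy one-to-one matching of detected onsets against expected onsets
# (schedule onset + channel delay); a hit lies in [expected - pre,
# expected + post].
schedule_f1 <- function(detected_onsets, expected_onsets, pre = 1, post = 4) {
  used <- rep(FALSE, length(detected_onsets))
  tp <- 0L
  for (o in expected_onsets) {
    cand <- which(!used & detected_onsets >= o - pre &
                    detected_onsets <= o + post)
    if (length(cand)) {
      used[cand[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- if (length(detected_onsets)) tp / length(detected_onsets) else 0
  rec <- if (length(expected_onsets)) tp / length(expected_onsets) else 1
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

empty_schedule <- function(duration = 300) {
  stressor_schedule(numeric(), numeric(), numeric(), numeric(), duration)
}

# binary stressor-state indicator sampled on a parameter series' grid
state_on_grid <- function(schedule, timestamps, delay = 0) {
  out <- numeric(length(timestamps))
  ev <- schedule$events
  for (i in seq_len(nrow(ev)))
    out[timestamps >= ev$onset[i] + delay &
        timestamps < ev$onset[i] + ev$duration[i] + delay] <- 1
  out
}
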