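# EEG time-frequency analysis: 8-25 Hz band-pass with artifact masking,
# 0.1 Hz-resolution spectrograms, band condensation (alpha1/alpha2/beta),
# slope and variance statistics, and z-score significant-channel counting.

TF_BANDS <- list(alpha1 = c(8, 12), alpha2 = c(13, 15), beta = c(16, 20))

#' Zero-phase EEG band-pass filter with artifact masking
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase); samples whose absolute filtered value exceeds the artifact
#' threshold are masked (set to `NA`).
#'
#' @param eeg a 256 Hz EEG [sensor_stream()].
#' @param lo,hi band edges, Hz (defaults 8 and 25).
#' @param artifact_uV artifact threshold in microvolts (default 100).
#' @return a filtered [sensor_stream()] with artifacts `NA`-masked.
#' @export
eeg_bandpass <- function(eeg, lo = 8, hi = 25, artifact_uV = 100) {
  fs <- eeg$nominal_rate
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  v <- as.numeric(signal::filtfilt(bf, eeg$values))
  v[abs(v) > artifact_uV] <- NA_real_
  sensor_stream(eeg$name, eeg$timestamps, v, fs, eeg$units)
}

#' Spectrogram at 0.1 Hz frequency resolution
#'
#' Short-time Hamming-tapered periodograms, zero-padded so that the
#' frequency axis has exactly 0.1 Hz spacing; the matrix is restricted to
#' `freq_range`. Windows containing more than 20% masked samples are
#' dropped; smaller amounts of masking are mean-imputed within the window.
#'
#' @param eeg a band-passed EEG [sensor_stream()].
#' @param window_s window length, seconds (default 10).
#' @param step_s hop, seconds (default 1).
#' @param freq_range frequencies retained, Hz (default 8-25).
#' @param max_masked_frac window drop threshold for masked samples.
#' @return an object of class `spectrogram`: `channel`, `times`, `freqs`
#'   (0.1 Hz spacing), `power` (time x freq, uV^2/Hz).
#' @export
spectrogram_01hz <- function(eeg, window_s = 10, step_s = 1,
                             freq_range = c(8, 25),
                             max_masked_frac = 0.2) {
  fs <- eeg$nominal_rate
  if (window_s < 2 / 0.1 * 0.5)
    warning("window shorter than the effective 0.1 Hz resolution support")
  wlen <- as.integer(round(window_s * fs))
  step <- as.integer(round(step_s * fs))
  nfft <- as.integer(round(fs / 0.1))          # exact 0.1 Hz bins
  v <- eeg$values
  n <- length(v)
  starts <- seq(1L, n - wlen + 1L, by = step)
  w <- hamming_window(wlen)
  freqs_all <- (seq_len(nfft %/% 2 + 1L) - 1L) * 0.1
  sel <- freqs_all >= freq_range[1L] & freqs_all <= freq_range[2L]
  keep_t <- logical(length(starts))
  pw <- matrix(NA_real_, length(starts), sum(sel))
  for (i in seq_along(starts)) {
    seg <- v[starts[i]:(starts[i] + wlen - 1L)]
    miss <- is.na(seg)
    if (mean(miss) > max_masked_frac) next
    if (any(miss)) seg[miss] <- mean(seg, na.rm = TRUE)
    pg <- periodogram(seg, fs, taper = w, nfft = nfft)
    pw[i, ] <- pg$psd[sel]
    keep_t[i] <- TRUE
  }
  structure(list(channel = eeg$name,
                 times = eeg$timestamps[starts[keep_t]] + window_s / 2,
                 freqs = freqs_all[sel],
                 power = pw[keep_t, , drop = FALSE]),
            class = "spectrogram")
}

#' Condense a spectrogram into the three bands of interest
#'
#' Per band (alpha1 8-12 Hz, alpha2 13-15 Hz, beta 16-20 Hz): the mean
#' power across the band's bins at each time step, the least-squares linear
#' slope of that series over time, and its sample variance.
#'
#' @param spec a [spectrogram_01hz()] result.
#' @param bands named list of band edges, Hz.
#' @return a list of class `band_series_set`: per band a list with
#'   `series`, `times`, `slope`, `variance`; plus `channel`.
#' @export
condense_bands <- function(spec, bands = TF_BANDS) {
  out <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    sel <- spec$freqs >= b[1L] & spec$freqs <= b[2L]
    s <- rowMeans(spec$power[, sel, drop = FALSE])
    sl <- if (length(s) > 1L)
      unname(stats::coef(stats::lm.fit(cbind(1, spec$times), s))[2L]) else 0
    list(band = bn, series = s, times = spec$times, slope = sl,
         variance = stats::var(s))
  })
  names(out) <- names(bands)
  structure(c(out, list(channel = spec$channel)), class = "band_series_set")
}

#' Count significantly activated channels by variance z-score
#'
#' For each condition, band and channel, the band-power variances of the N
#' datasets in the group are standardized (`z = |(v - mean) / sd|` across
#' datasets within channel/band/condition) and each dataset contributes one
#' count when its |z| satisfies the configured rule. The conventional rule
#' `"ge2"` counts outlying (significantly large) variances, `|z| >= 2`; the
#' alternative `"lt2"` counts `|z| < 2`.
#'
#' @param variances a data frame with columns `condition`, `band`,
#'   `channel`, `dataset`, `variance` (one row per dataset x channel x
#'   band x condition, e.g. collected from [condense_bands()]).
#' @param z_rule `"ge2"` or `"lt2"`.
#' @param z_threshold threshold on |z| (default 2).
#' @return an object of class `variance_count_table`: a data frame with
#'   one row per condition x band and one column per channel, plus the rule
#'   used.
#' @export
variance_count_table <- function(variances, z_rule = c("ge2", "lt2"),
                                 z_threshold = 2) {
  z_rule <- match.arg(z_rule)
  stopifnot(all(c("condition", "band", "channel", "dataset", "variance")
                %in% names(variances)))
  groups <- unique(variances[, c("condition", "band")])
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    cond <- groups$condition[g]; band <- groups$band[g]
    row <- stats::setNames(as.list(integer(length(EEG_CHANNELS))),
                           EEG_CHANNELS)
    for (ch in EEG_CHANNELS) {
      v <- variances$variance[variances$condition == cond &
                              variances$band == band &
                              variances$channel == ch]
      if (length(v) < 3L)
        stop("need at least 3 datasets per group (", cond, "/", band,
             "/", ch, ")")
      sdv <- stats::sd(v)
      if (sdv <= .Machine$double.eps) {
        warning("zero variance spread in group ", cond, "/", band, "/", ch,
                "; counts set to 0")
        next
      }
      z <- abs((v - mean(v)) / sdv)
      row[[ch]] <- if (z_rule == "ge2") sum(z >= z_threshold)
                   else sum(z < z_threshold)
    }
    rows[[g]] <- cbind(data.frame(condition = cond, band = band,
                                  stringsAsFactors = FALSE),
                       as.data.frame(row))
  }
  out <- do.call(rbind, rows)
  attr(out, "z_rule") <- z_rule
  class(out) <- c("variance_count_table", "data.frame")
  out
}

#' Hemispheric dominance summary of a variance count table
#'
#' Per condition and band, sums the counts of the left (F3, FC3, C3) and
#' right (F4, FC4, C4) channels and flags which hemisphere dominates.
#'
#' @param table a [variance_count_table()] (or same-shaped data frame).
#' @return data frame with columns `condition`, `band`, `left`, `right`,
#'   `dominance` (`"left"`, `"right"` or `"none"`).
#' @export
hemisphere_pattern_summary <- function(table) {
  left <- rowSums(as.matrix(table[, EEG_LEFT, drop = FALSE]))
  right <- rowSums(as.matrix(table[, EEG_RIGHT, drop = FALSE]))
  data.frame(condition = table$condition, band = table$band,
             left = left, right = right,
             dominance = ifelse(left > right, "left",
                                ifelse(right > left, "right", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}
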