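# Long-term characterizations: slow emotional-state measures on the scale
# of tens of seconds (blink counts, tonic skin conductance, LF/HF, and the
# meditation reference score).

PARAM_NAMES <- c("Blinkcount", "GSRSCL", "LFHF", "Meditation",
                 "GSRsiginc", "Blinksiginc", "medianRRI", "alphaAsym",
                 "Lever", "JoystickR2")

#' Named characterization series
#'
#' A time series of one physiological/behavioral characterization on the
#' analysis grid (or on per-window centers). Values may be `NA`
#' (missing-flagged).
#'
#' @param name one of Blinkcount, GSRSCL, LFHF, Meditation, GSRsiginc,
#'   Blinksiginc, medianRRI, alphaAsym, Lever, JoystickR2.
#' @param timestamps seconds, strictly increasing.
#' @param values numeric, same length.
#' @return an object of class `parameter_series`.
#' @export
parameter_series <- function(name, timestamps, values) {
  name <- match.arg(name, PARAM_NAMES)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  stopifnot(length(timestamps) == length(values))
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(name = name, timestamps = timestamps, values = values),
            class = "parameter_series")
}

#' @export
print.parameter_series <- function(x, ...) {
  cat(sprintf("<parameter_series '%s'> %d points, %d missing\n",
              x$name, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.parameter_series <- function(x) length(x$values)

#' Detect blink events from a blink-strength trace
#'
#' A blink event is an upward crossing of the strength signal above
#' `threshold` (of the 0-255 scale), with a refractory period between
#' events.
#'
#' @param blink_strength a 128 Hz (or similar) [sensor_stream()].
#' @param threshold crossing threshold on the 0-255 scale.
#' @param refractory minimum spacing between events, seconds.
#' @return an event-series [sensor_stream()] of blink times (values are the
#'   strengths at crossing).
#' @export
detect_blink_events <- function(blink_strength, threshold = 50,
                                refractory = 0.2) {
  v <- blink_strength$values
  t <- blink_strength$timestamps
  up <- which(v[-1L] > threshold & v[-length(v)] <= threshold) + 1L
  if (length(up) > 1L) {
    keep <- up[1L]
    for (i in up[-1L])
      if (t[i] - t[keep[length(keep)]] >= refractory) keep <- c(keep, i)
    up <- keep
  }
  sensor_stream("blink_strength", t[up], v[up], 0, "au")
}

#' Blink count per fixed interval
#'
#' Counts blink events in half-open bins of `bin_s` seconds.
#'
#' @param blink_events event-series [sensor_stream()] from
#'   [detect_blink_events()].
#' @param bin_s bin width, seconds (default 2).
#' @param duration total span to bin; defaults to the last event time.
#' @return a `parameter_series` named `"Blinkcount"`; timestamps are bin
#'   starts.
#' @export
blink_count <- function(blink_events, bin_s = 2, duration = NULL) {
  t <- blink_events$timestamps
  if (is.null(duration)) duration <- if (length(t)) max(t) + 1e-9 else bin_s
  edges <- seq(0, duration + bin_s, by = bin_s)
  counts <- as.numeric(table(factor(findInterval(t, edges),
                                    levels = seq_len(length(edges) - 1L))))
  parameter_series("Blinkcount", edges[-length(edges)], counts)
}

#' Tonic skin conductance level (SCL)
#'
#' Extracts the tonic/baseline electrodermal level as a running median,
#' which tracks slow drifts while attenuating short phasic responses.
#'
#' @param gsr a grid-rate [sensor_stream()] of skin conductance, uS.
#' @param window_s running-median window, seconds (default 30).
#' @return a `parameter_series` named `"GSRSCL"` on the input grid.
#' @export
gsr_scl <- function(gsr, window_s = 30) {
  v <- gsr$values
  if (all(is.na(v))) stop("all GSR samples missing")
  rate <- gsr$nominal_rate
  k <- as.integer(window_s * rate)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
  sm <- as.numeric(stats::runmed(v, k, endrule = "median"))
  parameter_series("GSRSCL", gsr$timestamps, sm)
}

#' Welch configuration for the LF/HF ratio
#'
#' @param window_s IBI analysis window, seconds (default 20).
#' @param n_segments,overlap Welch segmentation within each window.
#' @param lf_band,hf_band low- and high-frequency bands, Hz.
#' @param resample_rate uniform rate the event series is interpolated to
#'   before spectral analysis, Hz.
#' @return a list of class `welch_config`.
#' @export
welch_config <- function(window_s = 20, n_segments = 2L, overlap = 0.75,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                         resample_rate = 4) {
  stopifnot(lf_band[2L] <= resample_rate / 2, hf_band[2L] <= resample_rate / 2,
            lf_band[1L] > 0)
  structure(list(window_s = window_s, n_segments = as.integer(n_segments),
                 overlap = overlap, lf_band = lf_band, hf_band = hf_band,
                 resample_rate = resample_rate),
            class = "welch_config")
}

#' LF/HF ratio of heart-rate variability
#'
#' For each consecutive window of `cfg$window_s` seconds the inter-beat
#' intervals are linearly interpolated to a uniform rate, linearly
#' detrended, and a Welch PSD (Hamming-tapered overlapping segments) is
#' integrated over the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands; the
#' window's value is LF power / HF power. Windows with fewer than 2 beats
#' or negligible HF power are missing-flagged.
#'
#' @param ibi event-series [sensor_stream()] of RR intervals.
#' @param cfg a [welch_config()].
#' @return a `parameter_series` named `"LFHF"` at window centers.
#' @export
lfhf <- function(ibi, cfg = welch_config()) {
  stopifnot(ibi$nominal_rate == 0)
  dur <- max(ibi$timestamps)
  w <- cfg$window_s
  starts <- seq(0, dur - w, by = w)
  if (!length(starts)) stop("record shorter than one LF/HF window")
  vals <- rep(NA_real_, length(starts))
  n_skipped <- 0L
  for (i in seq_along(starts)) {
    lo <- starts[i]; hi <- lo + w
    sel <- ibi$timestamps >= lo & ibi$timestamps < hi
    if (sum(sel) < 2L) { n_skipped <- n_skipped + 1L; next }
    tt <- seq(lo, hi - 1 / cfg$resample_rate, by = 1 / cfg$resample_rate)
    rr <- stats::approx(ibi$timestamps[sel], ibi$values[sel], xout = tt,
                        rule = 2)$y
    rr <- stats::residuals(stats::lm.fit(cbind(1, tt), rr))  # detrend
    ps <- welch_psd(rr, cfg$resample_rate, cfg$n_segments, cfg$overlap)
    lf <- band_power(ps$freq, ps$psd, cfg$lf_band)
    hf <- band_power(ps$freq, ps$psd, cfg$hf_band)
    if (hf > .Machine$double.eps * max(lf, 1)) vals[i] <- lf / hf
  }
  if (n_skipped) message(n_skipped, " LF/HF window(s) with < 2 beats skipped")
  parameter_series("LFHF", starts + w / 2, vals)
}

#' Meditation score passthrough
#'
#' The proprietary relaxation score is treated as a trusted input channel:
#' values are clamped to `[0, 100]` (with a warning) and hold-resampled onto
#' the analysis grid.
#'
#' @param meditation a [sensor_stream()] of scores in `[0, 100]`.
#' @param grid_rate output rate, Hz; `NULL` keeps the input sampling.
#' @return a `parameter_series` named `"Meditation"`.
#' @export
meditation_series <- function(meditation, grid_rate = NULL) {
  if (!length(meditation$values)) stop("empty meditation stream")
  v <- meditation$values
  if (any(v < 0 | v > 100, na.rm = TRUE)) {
    warning("meditation values outside [0, 100] clamped")
    v <- pmin(pmax(v, 0), 100)
  }
  s <- sensor_stream(meditation$name, meditation$timestamps, v,
                     meditation$nominal_rate, meditation$units)
  if (!is.null(grid_rate) && grid_rate != s$nominal_rate)
    s <- resample_to_grid(s, grid_rate, "hold")
  parameter_series("Meditation", s$timestamps, s$values)
}
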