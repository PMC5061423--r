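# Short-term characterizations: moment-to-moment measures (square-wave
# encoding of significant slope increases, median RRI, frontal alpha
# asymmetry).

#' Slope-event detector configuration
#'
#' @param smooth_window_s running-mean smoothing window, seconds (GSR
#'   default 1.0; the blink-rate proxy uses 0.1).
#' @param slope_threshold_k threshold in multiples of the robust SD
#'   (1.4826 x median absolute deviation) of the signal derivative.
#' @param min_event_s minimum duration of a significant-increase run, s.
#' @param merge_gap_s runs closer than this are merged, s.
#' @return a list of class `slope_detector_config`.
#' @export
slope_detector_config <- function(smooth_window_s = 1.0,
                                  slope_threshold_k = 3,
                                  min_event_s = 0.5,
                                  merge_gap_s = 0.3) {
  stopifnot(smooth_window_s > 0, slope_threshold_k > 0, min_event_s >= 0)
  structure(list(smooth_window_s = smooth_window_s,
                 slope_threshold_k = slope_threshold_k,
                 min_event_s = min_event_s, merge_gap_s = merge_gap_s),
            class = "slope_detector_config")
}

#' Square-wave event series
#'
#' Encodes detected significant slope-increase runs: each event is a
#' rectangle whose width is the run duration and whose height is the
#' maximum signal amplitude reached during the run; everywhere else the
#' encoding is zero.
#'
#' @param onsets,widths,heights equal-length event vectors (seconds,
#'   seconds, signal units).
#' @param grid_timestamps timestamps of the underlying grid, used by
#'   [squarewave_to_grid()].
#' @param name characterization name for the grid encoding.
#' @return an object of class `squarewave_series`.
#' @export
squarewave_series <- function(onsets, widths, heights, grid_timestamps,
                              name = "GSRsiginc") {
  stopifnot(length(onsets) == length(widths),
            length(onsets) == length(heights), all(widths > 0))
  ord <- order(onsets)
  ev <- data.frame(onset = as.numeric(onsets)[ord],
                   width = as.numeric(widths)[ord],
                   height = as.numeric(heights)[ord])
  if (nrow(ev) > 1L &&
      any(ev$onset[-1L] < (ev$onset + ev$width)[-nrow(ev)] - 1e-9))
    stop("square-wave events overlap")
  structure(list(events = ev, grid_timestamps = grid_timestamps,
                 name = name),
            class = "squarewave_series")
}

#' @export
print.squarewave_series <- function(x, ...) {
  cat(sprintf("<squarewave_series '%s'> %d event(s)\n", x$name,
              nrow(x$events)))
  invisible(x)
}

#' Grid encoding of a square-wave series
#'
#' @param sw a [squarewave_series()].
#' @return a `parameter_series` equal to the event height inside each event
#'   window and zero elsewhere.
#' @export
squarewave_to_grid <- function(sw) {
  t <- sw$grid_timestamps
  v <- numeric(length(t))
  ev <- sw$events
  if (nrow(ev)) for (i in seq_len(nrow(ev))) {
    sel <- t >= ev$onset[i] & t < ev$onset[i] + ev$width[i]
    v[sel] <- ev$height[i]
  }
  parameter_series(sw$name, t, v)
}

#' Centered running mean
#'
#' Smooths by averaging neighboring points; edge windows shrink
#' symmetrically.
#'
#' @param x a [sensor_stream()].
#' @param window_s window length in seconds (at least 2 samples).
#' @return a smoothed [sensor_stream()].
#' @export
smooth_running_mean <- function(x, window_s) {
  w <- as.integer(round(window_s * x$nominal_rate))
  if (w < 2L) stop("smoothing window shorter than 2 samples")
  sensor_stream(x$name, x$timestamps, box_smooth(x$values, w),
                x$nominal_rate, x$units)
}

#' Detect significant slope increases and encode them as square waves
#'
#' The first-difference slope of the (already smoothed) signal is
#' thresholded at `slope_threshold_k` times its robust SD (1.4826 x MAD);
#' samples above threshold are merged into maximal runs (runs closer than
#' `merge_gap_s` are joined), runs shorter than `min_event_s` are dropped,
#' and each surviving run becomes one square-wave event with width equal to
#' the run duration and height equal to the maximum signal value within the
#' run. A flat signal (zero slope MAD) yields zero events with a warning.
#'
#' @param x a smoothed [sensor_stream()].
#' @param cfg a [slope_detector_config()].
#' @param name characterization name for the resulting series.
#' @return a [squarewave_series()].
#' @export
detect_sig_slope_increases <- function(x, cfg = slope_detector_config(),
                                       name = "GSRsiginc") {
  v <- x$values
  t <- x$timestamps
  dt <- 1 / x$nominal_rate
  slope <- diff(v) / dt
  sd_rob <- stats::mad(slope)          # 1.4826 * MAD, centered on median
  if (sd_rob <= .Machine$double.eps)   # sparse signals: MAD degenerates
    sd_rob <- stats::sd(slope)
  if (!is.finite(sd_rob) || sd_rob <= .Machine$double.eps) {
    warning("flat signal: slope spread is zero, no events detected")
    return(squarewave_series(numeric(), numeric(), numeric(), t, name))
  }
  thr <- cfg$slope_threshold_k * sd_rob
  hot <- slope > thr
  if (!any(hot))
    return(squarewave_series(numeric(), numeric(), numeric(), t, name))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(s = starts[r$values], e = ends[r$values])
  # merge runs separated by less than merge_gap_s
  if (nrow(runs) > 1L) {
    gap_smp <- cfg$merge_gap_s / dt
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      if (runs$s[i] - merged$e[nrow(merged)] <= gap_smp)
        merged$e[nrow(merged)] <- runs$e[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  on <- t[runs$s]
  wd <- t[pmin(runs$e + 1L, length(t))] - on
  keep <- wd >= cfg$min_event_s
  runs <- runs[keep, , drop = FALSE]; on <- on[keep]; wd <- wd[keep]
  ht <- vapply(seq_len(nrow(runs)), function(i)
    max(v[runs$s[i]:min(runs$e[i] + 1L, length(v))]), numeric(1))
  squarewave_series(on, wd, ht, t, name)
}

#' GSR significant-slope-increase characterization
#'
#' Composition of [smooth_running_mean()] (1 s default) and
#' [detect_sig_slope_increases()] applied to skin conductance.
#'
#' @param gsr a grid-rate GSR [sensor_stream()].
#' @param cfg a [slope_detector_config()].
#' @return a [squarewave_series()] named `"GSRsiginc"`.
#' @export
gsr_siginc <- function(gsr, cfg = slope_detector_config()) {
  sm <- smooth_running_mean(gsr, cfg$smooth_window_s)
  detect_sig_slope_increases(sm, cfg, name = "GSRsiginc")
}

#' Blink significant-slope-increase characterization
#'
#' The blink-rate proxy is a 0.1 s running mean of the 0-255 blink-strength
#' trace; its significant slope increases are encoded as square waves.
#'
#' @param blink_strength a 128 Hz [sensor_stream()].
#' @param cfg a [slope_detector_config()]; the default uses a 0.1 s
#'   smoothing window.
#' @return a [squarewave_series()] named `"Blinksiginc"`.
#' @export
blink_siginc <- function(blink_strength,
                         cfg = slope_detector_config(smooth_window_s = 0.1,
                                                     min_event_s = 0.05)) {
  sm <- smooth_running_mean(blink_strength, cfg$smooth_window_s)
  detect_sig_slope_increases(sm, cfg, name = "Blinksiginc")
}

#' Median RRI (reciprocal of the windowed median RR interval)
#'
#' For each sliding window the median RR interval is taken and inverted, so
#' higher values imply more arousal (faster heart rate).
#'
#' @param ibi event-series [sensor_stream()] of RR intervals.
#' @param window_s sliding window, seconds (default 5).
#' @param step_s output step, seconds (default 0.1, the 10 Hz grid).
#' @return a `parameter_series` named `"medianRRI"` in 1/s; windows with no
#'   beat are missing-flagged.
#' @export
median_rri <- function(ibi, window_s = 5, step_s = 0.1) {
  stopifnot(ibi$nominal_rate == 0)
  dur <- max(ibi$timestamps)
  centers <- seq(0, dur, by = step_s)
  bt <- ibi$timestamps
  rr <- ibi$values
  lo <- findInterval(centers - window_s / 2, bt) + 1L
  hi <- findInterval(centers + window_s / 2 - 1e-12, bt)
  vals <- rep(NA_real_, length(centers))
  for (i in seq_along(centers)) {
    if (hi[i] >= lo[i])
      vals[i] <- 1 / stats::median(rr[lo[i]:hi[i]])
  }
  parameter_series("medianRRI", centers, vals)
}

#' Frontal alpha asymmetry
#'
#' Per sliding window, alpha (8-13 Hz) band power is computed for each
#' channel from a short-window periodogram, averaged within each
#' hemisphere (left: F3, FC3, C3; right: F4, FC4, C4), and the value is
#' right minus left.
#'
#' @param eeg named list of six EEG [sensor_stream()]s.
#' @param window_s sliding window, seconds (default 2).
#' @param step_s output step, seconds (default 0.1).
#' @param band alpha band, Hz.
#' @return a `parameter_series` named `"alphaAsym"`.
#' @export
alpha_asymmetry <- function(eeg, window_s = 2, step_s = 0.1,
                            band = c(8, 13)) {
  missing_ch <- setdiff(EEG_CHANNELS, names(eeg))
  if (length(missing_ch))
    stop("missing EEG channel(s): ", paste(missing_ch, collapse = ", "))
  fs <- eeg[[EEG_CHANNELS[1L]]]$nominal_rate
  t0 <- eeg[[EEG_CHANNELS[1L]]]$timestamps[1L]
  n <- length(eeg[[EEG_CHANNELS[1L]]]$values)
  wlen <- as.integer(round(window_s * fs))
  step <- max(1L, as.integer(round(step_s * fs)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  centers <- t0 + (starts - 1L + wlen / 2) / fs
  pow <- matrix(0, length(starts), 6L,
                dimnames = list(NULL, EEG_CHANNELS))
  for (ch in EEG_CHANNELS) {
    v <- eeg[[ch]]$values
    for (i in seq_along(starts))
      pow[i, ch] <- segment_band_power(v[starts[i]:(starts[i] + wlen - 1L)],
                                       fs, band)
  }
  asym <- rowMeans(pow[, EEG_RIGHT, drop = FALSE]) -
          rowMeans(pow[, EEG_LEFT, drop = FALSE])
  parameter_series("alphaAsym", centers, asym)
}
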