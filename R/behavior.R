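# Behavioral preprocessing and stressor-interval label construction.

# (source, interval) combinations tested in the study design
LABEL_INTERVALS <- list(GSRsiginc = c(2, 4), medianRRI = c(2, 5),
                        GSRSCL = c(2, 5), Meditation = c(2, 5),
                        Joystick = 5)

#' Joystick smoothness score (coefficient of determination)
#'
#' The forward/backward joystick position is smoothed with a running mean
#' over `2M + 1` successive points; per sliding window the agreement between
#' the actual and smoothed trace is scored as
#' `R^2 = 1 - sum((x - xhat)^2) / sum((x - xbar)^2)`, clipped to `[0, 1]`.
#' Smooth manipulation gives values near 1, jerky manipulation markedly
#' lower ones. Windows with zero variance are perfectly smooth by
#' convention (`R^2 = 1`) and flagged.
#'
#' @param y a grid-rate joystick [sensor_stream()].
#' @param M one-sided smoothing half-length in samples (default 5).
#' @param window_s sliding window, seconds (default 5).
#' @param step_s output step, seconds (default 0.1).
#' @return a `parameter_series` named `"JoystickR2"` with attribute
#'   `"degenerate"` marking zero-variance windows.
#' @export
joystick_r2 <- function(y, M = 5, window_s = 5, step_s = 0.1) {
  stopifnot(M >= 1)
  n <- length(y$values)
  if (n < 2 * M + 1) stop("stream shorter than 2M + 1 samples")
  xhat <- box_smooth(y$values, 2L * M + 1L)
  rate <- y$nominal_rate
  wlen <- as.integer(round(window_s * rate))
  step <- max(1L, as.integer(round(step_s * rate)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  vals <- numeric(length(starts))
  degen <- logical(length(starts))
  x <- y$values
  for (i in seq_along(starts)) {
    ix <- starts[i]:(starts[i] + wlen - 1L)
    ss_tot <- sum((x[ix] - mean(x[ix]))^2)
    if (ss_tot <= .Machine$double.eps) {
      vals[i] <- 1; degen[i] <- TRUE
    } else {
      r2 <- 1 - sum((x[ix] - xhat[ix])^2) / ss_tot
      vals[i] <- min(max(r2, 0), 1)
    }
  }
  out <- parameter_series("JoystickR2",
                          y$timestamps[starts] + (wlen - 1L) / (2 * rate),
                          vals)
  attr(out, "degenerate") <- degen
  out
}

#' Min-max normalize a characterization to [0, 1]
#'
#' @param p a `parameter_series`.
#' @return the series rescaled as `(x - min) / (max - min)`; `NA`s are
#'   preserved.
#' @export
normalize_series <- function(p) {
  v <- p$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= .Machine$double.eps)
    stop("cannot normalize a constant series")
  out <- p
  out$values <- (v - rng[1L]) / diff(rng)
  out
}

#' Label specification
#'
#' @param source label source characterization: `"GSRsiginc"`,
#'   `"medianRRI"`, `"GSRSCL"`, `"Meditation"` or `"Joystick"`.
#' @param interval_s stressor-interval duration, seconds; must belong to
#'   the source's tested set (GSRsiginc 2/4; medianRRI, GSRSCL, Meditation
#'   2/5; Joystick 5).
#' @param cutoff_rule `"mean_of_series"`, `"median_of_series"`,
#'   `"fixed"` (with `fixed_cutoff`), or `NULL` for the source's default
#'   rule (mean for GSRsiginc/GSRSCL/Joystick, median for medianRRI, fixed
#'   50 for Meditation).
#' @param fixed_cutoff cutoff value when `cutoff_rule = "fixed"`.
#' @return a list of class `label_spec`.
#' @export
label_spec <- function(source, interval_s, cutoff_rule = NULL,
                       fixed_cutoff = 50) {
  source <- match.arg(source, names(LABEL_INTERVALS))
  if (!interval_s %in% LABEL_INTERVALS[[source]])
    stop("interval ", interval_s, " s is not in the tested set for ",
         source, " (allowed: ",
         paste(LABEL_INTERVALS[[source]], collapse = ", "), ")")
  if (is.null(cutoff_rule))
    cutoff_rule <- switch(source, medianRRI = "median_of_series",
                          Meditation = "fixed", "mean_of_series")
  cutoff_rule <- match.arg(cutoff_rule,
                           c("mean_of_series", "median_of_series", "fixed"))
  structure(list(source = source, interval_s = interval_s,
                 cutoff_rule = cutoff_rule, fixed_cutoff = fixed_cutoff),
            class = "label_spec")
}

#' Construct stressor-interval labels
#'
#' The preprocessed characterization is divided into equal-sized successive
#' intervals of `spec$interval_s` seconds (a trailing partial interval is
#' dropped); interval means above the cutoff are labeled 2 (absence of a
#' stressor), means at or below it 1 (presence of a stressor).
#'
#' @param p a `parameter_series` (normalized as appropriate for the source).
#' @param spec a [label_spec()].
#' @return a data frame of class `label_series` with columns
#'   `interval_start_s`, `label` (1 = presence, 2 = absence), and
#'   attributes `cutoff_used`, `interval_s`, `source`.
#' @export
build_labels <- function(p, spec) {
  v <- p$values
  t <- p$timestamps
  cutoff <- switch(spec$cutoff_rule,
                   mean_of_series = mean(v, na.rm = TRUE),
                   median_of_series = stats::median(v, na.rm = TRUE),
                   fixed = spec$fixed_cutoff)
  dt <- stats::median(diff(t))
  t0 <- t[1L]
  nper <- as.integer(round(spec$interval_s / dt))
  nint <- length(v) %/% nper
  if (nint < 1L) stop("series shorter than one stressor-interval")
  means <- vapply(seq_len(nint), function(k)
    mean(v[((k - 1L) * nper + 1L):(k * nper)], na.rm = TRUE), numeric(1))
  labels <- ifelse(means > cutoff, 2L, 1L)   # tie (==) goes to presence
  out <- data.frame(interval_start_s = t0 + (seq_len(nint) - 1L) *
                      spec$interval_s,
                    label = labels)
  attr(out, "cutoff_used") <- cutoff
  attr(out, "interval_s") <- spec$interval_s
  attr(out, "source") <- spec$source
  class(out) <- c("label_series", "data.frame")
  out
}

#' Preprocess the evaluation lever
#'
#' The continuous self-report lever is rectified (absolute value, arousal
#' magnitude) and normalized to `[0, 1]`; an all-zero lever stays zero.
#'
#' @param lever a grid-rate lever [sensor_stream()].
#' @return a `parameter_series` named `"Lever"`.
#' @export
lever_preprocess <- function(lever) {
  v <- abs(lever$values)
  mx <- max(v, na.rm = TRUE)
  if (mx > 0) v <- v / mx
  parameter_series("Lever", lever$timestamps, v)
}
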