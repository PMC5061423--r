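# Synthetic multimodal cohort: every downstream stage is validated against
# the ground-truth stressor schedules generated here.

derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 16807 + as.double(x)) %% 2147483647
  as.integer(s)
}

# seed the RNG for a function body without clobbering the caller's
# stream: returns a restorer to register with on.exit
local_seed <- function(seed) {
  prev <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  function() {
    if (!is.null(prev)) assign(".Random.seed", prev, globalenv())
  }
}

#' Stressor schedule
#'
#' Event-based stressor model: sudden, time-limited stressors with an onset,
#' duration, intensity in `[0, 1]` and a valence sign.
#'
#' @param onsets,durations,intensities,valence_signs equal-length vectors;
#'   `valence_signs` entries are -1 or +1.
#' @param session_duration total session length in seconds.
#' @return an object of class `stressor_schedule` (a data frame of events
#'   plus the session duration).
#' @export
stressor_schedule <- function(onsets, durations, intensities,
                              valence_signs, session_duration) {
  ord <- order(onsets)
  ev <- data.frame(onset = as.numeric(onsets)[ord],
                   duration = as.numeric(durations)[ord],
                   intensity = as.numeric(intensities)[ord],
                   valence_sign = as.numeric(valence_signs)[ord])
  stopifnot(all(ev$intensity >= 0 & ev$intensity <= 1),
            all(ev$valence_sign %in% c(-1, 1)),
            all(ev$onset >= 0 & ev$onset < session_duration))
  if (nrow(ev) > 1L &&
      any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)]))
    stop("stressor events overlap")
  structure(list(events = ev, session_duration = session_duration),
            class = "stressor_schedule")
}

#' @export
print.stressor_schedule <- function(x, ...) {
  cat(sprintf("<stressor_schedule> %d event(s) over %.0f s\n",
              nrow(x$events), x$session_duration))
  invisible(x)
}

#' Draw a random non-overlapping stressor schedule
#'
#' Events are scattered uniformly subject to a minimum gap, with durations
#' drawn uniformly from `duration_range` and intensities from
#' `intensity_range`.
#'
#' @param duration session duration in seconds.
#' @param n_events number of stressor events.
#' @param min_gap minimum spacing between the end of one event and the onset
#'   of the next, in seconds.
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @param duration_range,intensity_range ranges for event duration (s) and
#'   intensity.
#' @param valence_sign fixed valence sign for all events (-1 for negative).
#' @return a [stressor_schedule()].
#' @export
make_schedule <- function(duration, n_events, min_gap = 10, seed = 1,
                          duration_range = c(5, 10),
                          intensity_range = c(0.7, 1),
                          valence_sign = -1) {
  if (n_events == 0L)
    return(stressor_schedule(numeric(), numeric(), numeric(), numeric(),
                             duration))
  mean_dur <- mean(duration_range)
  if (n_events * (mean_dur + min_gap) > duration)
    stop("infeasible packing: ", n_events, " events of mean ", mean_dur,
         " s with gap ", min_gap, " s do not fit in ", duration, " s")
  restore_rng <- local_seed(derive_seed(seed, 101))
  on.exit(restore_rng(), add = TRUE)
  durs <- stats::runif(n_events, duration_range[1L], duration_range[2L])
  # place by distributing the free (unoccupied) time uniformly between events
  free <- duration - sum(durs) - (n_events - 1L) * min_gap - min_gap
  g <- stats::runif(n_events + 1L)
  gaps <- g / sum(g) * free        # slack before, between and after events
  inc <- c(gaps[1L] + min_gap / 2,
           if (n_events > 1L)
             durs[seq_len(n_events - 1L)] + min_gap + gaps[2:n_events])
  onsets <- pmin(cumsum(inc), duration - durs - 1e-6)
  stressor_schedule(onsets, durs,
                    stats::runif(n_events, intensity_range[1L],
                                 intensity_range[2L]),
                    rep(valence_sign, n_events), duration)
}

#' Participant response profile
#'
#' Gains, baselines and per-channel response delays of a simulated
#' participant. The defaults encode the stimulus-response structure the
#' analysis assumes: the skin-conductance response trails the lever by about
#' 2 s while the cardiac and blink responses trail it by 6.5 s and 4.65 s.
#'
#' @param scl_baseline tonic skin conductance level, microsiemens.
#' @param scr_gain phasic response amplitude per unit intensity, uS.
#' @param ibi_baseline resting inter-beat interval, seconds (0.5-1.5 s).
#' @param ibi_drop IBI shortening per unit intensity at response peak, s.
#' @param lf_amp,hf_amp relative depths of the 0.1 Hz and 0.3 Hz IBI
#'   modulations (low- and high-frequency HRV structure).
#' @param alpha_amp EEG alpha (10 Hz) amplitude, microvolts.
#' @param asymmetry_gain fractional right-minus-left alpha modulation during
#'   stressor state.
#' @param blink_base_rate spontaneous blink rate, Hz.
#' @param habituation_rate multiplicative per-exposure response decay in
#'   `(0, 1]`; 1 disables habituation.
#' @param delays named numeric vector of response lags (s) for `gsr`,
#'   `heart`, `blink`, `lever`.
#' @return an object of class `participant_profile`.
#' @export
participant_profile <- function(scl_baseline = 5, scr_gain = 2,
                                ibi_baseline = 0.8, ibi_drop = 0.15,
                                lf_amp = 0.02, hf_amp = 0.02,
                                alpha_amp = 10, asymmetry_gain = 0.5,
                                blink_base_rate = 0.2,
                                habituation_rate = 0.8,
                                delays = c(gsr = 2.0, heart = 6.5,
                                           blink = 4.65, lever = 0.0)) {
  stopifnot(scr_gain >= 0, ibi_drop >= 0, alpha_amp >= 0,
            blink_base_rate >= 0,
            habituation_rate > 0, habituation_rate <= 1,
            ibi_baseline >= 0.5, ibi_baseline <= 1.5)
  d <- c(gsr = 2.0, heart = 6.5, blink = 4.65, lever = 0.0)
  d[names(delays)] <- delays
  structure(list(scl_baseline = scl_baseline, scr_gain = scr_gain,
                 ibi_baseline = ibi_baseline, ibi_drop = ibi_drop,
                 lf_amp = lf_amp, hf_amp = hf_amp, alpha_amp = alpha_amp,
                 asymmetry_gain = asymmetry_gain,
                 blink_base_rate = blink_base_rate,
                 habituation_rate = habituation_rate, delays = d),
            class = "participant_profile")
}

#' Simulation configuration
#'
#' Fixes cohort shape, schedule parameters, per-channel noise levels and the
#' master seed; identical configurations yield byte-identical cohorts.
#'
#' @param n_participants,trials,loops cohort shape.
#' @param seed master integer seed.
#' @param duration session duration in seconds.
#' @param n_events stressor events per session.
#' @param min_gap minimum inter-event gap, s.
#' @param grid_rate common analysis grid, Hz.
#' @param noise named list of noise levels: `gsr` (uS), `ibi` (s),
#'   `eeg` (uV, 1/f process SD), `meditation` (score units),
#'   `joystick_base` and `joystick_jitter` (a.u. SD at rest / per unit
#'   stressor intensity).
#' @param channels channel groups to generate (subset of
#'   `c("gsr","ibi","eeg","blink","lever","joystick","meditation")`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 15, trials = 3, loops = 1,
                       seed = 1, duration = 300, n_events = 6,
                       min_gap = 10, grid_rate = 10,
                       noise = list(), channels = NULL) {
  def <- list(gsr = 0.015, ibi = 0.004, eeg = 5, meditation = 2,
              joystick_base = 0.005, joystick_jitter = 0.08)
  unknown <- setdiff(names(noise), names(def))
  if (length(unknown))
    stop("unknown noise field(s): ", paste(unknown, collapse = ", "))
  def[names(noise)] <- noise
  all_ch <- c("gsr", "ibi", "eeg", "blink", "lever", "joystick", "meditation")
  if (is.null(channels)) channels <- all_ch
  stopifnot(all(channels %in% all_ch))
  structure(list(n_participants = as.integer(n_participants),
                 trials = as.integer(trials), loops = as.integer(loops),
                 seed = as.integer(seed), duration = duration,
                 n_events = as.integer(n_events), min_gap = min_gap,
                 grid_rate = grid_rate, noise = def, channels = channels),
            class = "sim_config")
}

# intensity-valued stressor state at times t, optionally delayed
schedule_state <- function(schedule, t, delay = 0, binary = FALSE) {
  out <- numeric(length(t))
  ev <- schedule$events
  if (nrow(ev)) for (i in seq_len(nrow(ev))) {
    inwin <- t >= ev$onset[i] + delay & t < ev$onset[i] + ev$duration[i] + delay
    out[inwin] <- if (binary) 1 else ev$intensity[i]
  }
  out
}

# difference-of-exponentials response kernel, normalized to unit peak
scr_kernel <- function(t, rise = 0.75, decay = 4) {
  k <- ifelse(t < 0, 0, exp(-t / decay) - exp(-t / rise))
  tpk <- log(decay / rise) / (1 / rise - 1 / decay)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

# sustained response: the kernel convolved with the event boxcar
# (response builds while the stressor lasts, then decays), unit peak
boxcar_response <- function(t, onset, duration, delay = 0,
                            rise = 0.75, decay = 4) {
  shape <- function(tp) {
    m <- pmin(tp, duration)
    r <- decay * (exp(-(tp - m) / decay) - exp(-tp / decay)) -
         rise * (exp(-(tp - m) / rise) - exp(-tp / rise))
    ifelse(tp <= 0, 0, r)
  }
  pk <- max(shape(seq(0, duration + 3 * decay, length.out = 400L)))
  shape(t - onset - delay) / pk
}

# centered running mean with shrinking edge windows (see characterize_short)
box_smooth <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate electrodermal activity
#'
#' Tonic level = slow drift around the baseline skin conductance level; each
#' scheduled stressor adds a sustained phasic response — the
#' difference-of-exponentials kernel (rise 0.75 s, decay 4 s) convolved
#' with the stressor window, so conductance builds while the stressor lasts
#' and decays after it ends — delayed by the profile's GSR lag, with peak
#' amplitude `scr_gain * intensity * habituation_rate^exposure_index`, plus
#' additive Gaussian noise.
#'
#' @param schedule a [stressor_schedule()].
#' @param profile a [participant_profile()].
#' @param exposure_index 0-based count of prior exposures driving
#'   habituation.
#' @param seed integer seed.
#' @param grid_rate output rate, Hz (at least 4).
#' @param noise_sd additive noise SD, uS.
#' @return a 10 Hz (by default) [sensor_stream()] named `"gsr"`.
#' @export
simulate_gsr <- function(schedule, profile, exposure_index = 0, seed = 1,
                         grid_rate = 10, noise_sd = 0.02) {
  stopifnot(grid_rate >= 4)
  restore_rng <- local_seed(derive_seed(seed, 11))
  on.exit(restore_rng(), add = TRUE)
  t <- seq(0, schedule$session_duration, by = 1 / grid_rate)
  ph <- stats::runif(2, 0, 2 * pi)
  tonic <- profile$scl_baseline +
    0.10 * sin(2 * pi * t / 300 + ph[1L]) +
    0.05 * sin(2 * pi * t / 120 + ph[2L])
  phasic <- numeric(length(t))
  hab <- profile$habituation_rate^exposure_index
  ev <- schedule$events
  if (nrow(ev)) for (i in seq_len(nrow(ev))) {
    amp <- profile$scr_gain * ev$intensity[i] * hab
    phasic <- phasic +
      amp * boxcar_response(t, ev$onset[i], ev$duration[i],
                            profile$delays[["gsr"]])
  }
  v <- tonic + phasic + stats::rnorm(length(t), 0, noise_sd)
  sensor_stream("gsr", t, v, grid_rate, "uS")
}

#' Simulate an inter-beat-interval event series
#'
#' The instantaneous IBI carries sinusoidal low-frequency (0.1 Hz) and
#' high-frequency (0.3 Hz) modulations of relative depth `lf_amp` / `hf_amp`
#' around `ibi_baseline`, and each stressor shortens it by up to
#' `ibi_drop * intensity` for the duration of the event (sustained response
#' kernel delayed by the profile's cardiac lag). Beats are produced by integrate-and-fire on the instantaneous IBI.
#'
#' @inheritParams simulate_gsr
#' @param noise_sd per-beat Gaussian jitter SD, seconds.
#' @return an event-series [sensor_stream()] named `"ibi_event"`: timestamps
#'   are beat times, values the preceding RR interval in seconds.
#' @export
simulate_ibi <- function(schedule, profile, exposure_index = 0, seed = 1,
                         noise_sd = 0.004) {
  restore_rng <- local_seed(derive_seed(seed, 13))
  on.exit(restore_rng(), add = TRUE)
  dur <- schedule$session_duration
  hab <- profile$habituation_rate^exposure_index
  ev <- schedule$events
  tg <- seq(0, dur + 2, by = 0.1)
  drop <- numeric(length(tg))
  if (nrow(ev)) for (i in seq_len(nrow(ev)))
    drop <- drop + profile$ibi_drop * ev$intensity[i] * hab *
      boxcar_response(tg, ev$onset[i], ev$duration[i],
                      profile$delays[["heart"]], rise = 0.5, decay = 2)
  ibi_at <- function(tt) {
    profile$ibi_baseline *
      (1 + profile$lf_amp * sin(2 * pi * 0.1 * tt) +
           profile$hf_amp * sin(2 * pi * 0.3 * tt)) -
      stats::approx(tg, drop, xout = tt, rule = 2)$y
  }
  # sanity: kernel peak is 1, so worst-case IBI is baseline*(1-lf-hf)-drop
  floor_ibi <- profile$ibi_baseline *
    (1 - profile$lf_amp - profile$hf_amp) - profile$ibi_drop * hab
  if (floor_ibi <= 0.3)
    stop("non-physiological parameters: instantaneous IBI can fall below 0.3 s")
  beats <- numeric(ceiling(dur / (0.3)))
  n <- 0L
  tcur <- 0
  repeat {
    rr <- ibi_at(tcur) + stats::rnorm(1L, 0, noise_sd)
    rr <- max(rr, 0.31)
    tcur <- tcur + rr
    if (tcur > dur) break
    n <- n + 1L
    beats[n] <- tcur
  }
  beats <- beats[seq_len(n)]
  if (n < 2L) stop("session too short for beat generation")
  sensor_stream("ibi_event", beats[-1L], diff(beats), 0, "s")
}

# 1/f ("pink") noise via spectral shaping, unit variance.
# Generated at an FFT-friendly length (2^a 3^b 5^c) and truncated.
pink_noise <- function(n, fs) {
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(1e-3, seq_len(m - 1L)) * fs / m
  f <- pmin(f, fs - f)          # mirror for the negative-frequency half
  f[f <= 0] <- fs / m
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / m
  as.numeric(scale(x[seq_len(n)]))
}

#' Simulate six-channel EEG
#'
#' Each channel is 1/f background noise plus a 10 Hz alpha rhythm whose
#' amplitude is modulated in opposite directions on the two hemispheres
#' while a stressor is present: right channels (F4, FC4, C4) gain
#' `alpha_amp * asymmetry_gain/2`, left channels lose it, producing positive
#' right-minus-left alpha power during stressor state (no response lag —
#' central response). A mild global alpha suppression (15% at full
#' intensity, classic arousal-related alpha blocking) rides on top of the
#' asymmetry, so absolute channel powers carry stressor information that
#' pure left-right differences cancel out. Left channels additionally get a small 18 Hz beta
#' bump inside stressor windows. The asymmetry modulation habituates with
#' `habituation_rate^exposure_index`.
#'
#' @inheritParams simulate_gsr
#' @param fs sampling rate, Hz.
#' @param noise_sd SD of the 1/f background, uV.
#' @return named list of six 256 Hz [sensor_stream()]s (F3, FC3, C3, F4,
#'   FC4, C4).
#' @export
simulate_eeg <- function(schedule, profile, exposure_index = 0, seed = 1,
                         fs = 256, noise_sd = 5) {
  dur <- schedule$session_duration
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  state <- schedule_state(schedule, t, delay = 0, binary = TRUE)
  hab <- profile$habituation_rate^exposure_index
  g <- profile$asymmetry_gain * hab
  sup <- 0.15 * hab
  out <- list()
  restore_rng <- local_seed(derive_seed(seed, 17))
  on.exit(restore_rng(), add = TRUE)
  for (ch in EEG_CHANNELS) {
    set.seed(derive_seed(seed, 17, match(ch, EEG_CHANNELS)))
    sgn <- if (ch %in% EEG_RIGHT) 1 else -1
    # global alpha blocking under arousal plus the hemispheric asymmetry;
    # both habituate with repeated exposure
    amp <- profile$alpha_amp * (1 - sup * state) *
      (1 + sgn * g * state / 2)
    ph <- stats::runif(2, 0, 2 * pi)
    # spontaneous alpha waxing/waning: lognormal envelope, ~1 s time scale
    z <- box_smooth(stats::rnorm(n), fs)
    z <- 0.5 * z / stats::sd(z)
    env <- exp(z - 0.125)
    v <- noise_sd * pink_noise(n, fs) +
      amp * env * sin(2 * pi * 10 * t + ph[1L])
    if (ch %in% EEG_LEFT)
      v <- v + 0.3 * profile$alpha_amp * hab * state * sin(2 * pi * 18 * t + ph[2L])
    out[[ch]] <- sensor_stream(ch, t, v, fs, "uV")
  }
  out
}

#' Simulate Mindwave-style blink strength
#'
#' Spontaneous blinks follow a Poisson process at `blink_base_rate`,
#' multiplied by `(1 + intensity)` inside stressor windows shifted by the
#' profile's blink lag. Each blink is a short half-sine pulse with peak
#' strength in `[0, 255]`.
#'
#' @inheritParams simulate_gsr
#' @param fs sampling rate, Hz.
#' @return a 128 Hz [sensor_stream()] named `"blink_strength"`.
#' @export
simulate_blinks <- function(schedule, profile, exposure_index = 0, seed = 1,
                            fs = 128) {
  restore_rng <- local_seed(derive_seed(seed, 19))
  on.exit(restore_rng(), add = TRUE)
  dur <- schedule$session_duration
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  v <- numeric(n)
  if (profile$blink_base_rate > 0) {
    rate <- profile$blink_base_rate *
      (1 + schedule_state(schedule, t, delay = profile$delays[["blink"]]))
    hit <- which(stats::runif(n) < rate / fs)
    # refractory 0.25 s between blink onsets
    if (length(hit) > 1L) {
      keep <- hit[1L]
      for (i in hit[-1L]) if (t[i] - t[keep[length(keep)]] >= 0.25)
        keep <- c(keep, i)
      hit <- keep
    }
    pulse_n <- round(0.15 * fs)
    pulse <- sin(pi * seq_len(pulse_n) / pulse_n)
    for (i in hit) {
      s <- stats::runif(1L, 120, 250)
      ix <- i:min(i + pulse_n - 1L, n)
      v[ix] <- pmax(v[ix], s * pulse[seq_along(ix)])
    }
  }
  v <- pmin(pmax(v, 0), 255)
  sensor_stream("blink_strength", t, v, fs, "au")
}

#' Simulate the evaluation lever
#'
#' The lever reports `intensity * valence_sign` inside stressor windows
#' (zero response lag), zero elsewhere, with rises and falls smoothed over
#' 0.5 s.
#'
#' @inheritParams simulate_gsr
#' @return a 10 Hz [sensor_stream()] named `"lever"`.
#' @export
simulate_lever <- function(schedule, profile, seed = 1, grid_rate = 10) {
  t <- seq(0, schedule$session_duration, by = 1 / grid_rate)
  v <- numeric(length(t))
  ev <- schedule$events
  if (nrow(ev)) for (i in seq_len(nrow(ev))) {
    inwin <- t >= ev$onset[i] + profile$delays[["lever"]] &
      t < ev$onset[i] + ev$duration[i] + profile$delays[["lever"]]
    v[inwin] <- ev$intensity[i] * ev$valence_sign[i]
  }
  v <- box_smooth(v, round(0.5 * grid_rate))
  sensor_stream("lever", t, v, grid_rate, "au")
}

#' Simulate joystick forward/backward position
#'
#' A smooth low-frequency base trajectory plus white jitter whose SD is
#' `joystick_base` at rest and grows by `joystick_jitter * intensity` while
#' a stressor is present (jerky manipulation under stress).
#'
#' @inheritParams simulate_gsr
#' @param base_sd,jitter_gain rest jitter SD and per-unit-intensity jitter
#'   gain, a.u.
#' @return a 10 Hz [sensor_stream()] named `"joystick_y"`.
#' @export
simulate_joystick <- function(schedule, profile, seed = 1, grid_rate = 10,
                              base_sd = 0.005, jitter_gain = 0.08) {
  restore_rng <- local_seed(derive_seed(seed, 23))
  on.exit(restore_rng(), add = TRUE)
  t <- seq(0, schedule$session_duration, by = 1 / grid_rate)
  ph <- stats::runif(2, 0, 2 * pi)
  base <- 0.3 * sin(2 * pi * t / 23 + ph[1L]) +
          0.15 * sin(2 * pi * t / 9 + ph[2L]) + 0.5
  sdv <- base_sd + jitter_gain * schedule_state(schedule, t)
  v <- base + stats::rnorm(length(t), 0, 1) * sdv
  sensor_stream("joystick_y", t, v, grid_rate, "au")
}

simulate_meditation <- function(schedule, seed = 1, grid_rate = 10,
                                noise_sd = 2) {
  restore_rng <- local_seed(derive_seed(seed, 29))
  on.exit(restore_rng(), add = TRUE)
  t <- seq(0, schedule$session_duration, by = 1 / grid_rate)
  state <- schedule_state(schedule, t, binary = TRUE)
  sm <- box_smooth(state, round(5 * grid_rate))
  v <- 100 * (1 - sm) + stats::rnorm(length(t), 0, noise_sd)
  sensor_stream("meditation", t, pmin(pmax(v, 0), 100), grid_rate, "au")
}

#' Simulate one full session
#'
#' Generates every channel of a session from a single stressor schedule on a
#' common clock. Rest sessions get an empty schedule and no lever/joystick
#' channels; autonomous sessions carry the lever, self-driving sessions the
#' joystick. The meditation score is emulated as
#' `100 * (1 - smoothed stressor state)`.
#'
#' @param meta a [session_meta()].
#' @param schedule a [stressor_schedule()]; ignored (replaced by an empty
#'   schedule) for rest sessions.
#' @param profile a [participant_profile()].
#' @param config a [sim_config()]; its `channels` field selects which groups
#'   to generate, its `noise` field sets channel noise.
#' @param exposure_index 0-based prior-exposure count driving habituation.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [session()].
#' @export
simulate_session <- function(meta, schedule, profile, config,
                             exposure_index = 0, seed = config$seed) {
  if (meta$modality == "rest")
    schedule <- stressor_schedule(numeric(), numeric(), numeric(), numeric(),
                                  schedule$session_duration)
  ch <- config$channels
  gr <- config$grid_rate
  ns <- config$noise
  st <- list()
  if ("gsr" %in% ch)
    st$gsr <- simulate_gsr(schedule, profile, exposure_index, seed,
                           gr, ns$gsr)
  if ("ibi" %in% ch)
    st$ibi_event <- simulate_ibi(schedule, profile, exposure_index, seed,
                                 ns$ibi)
  if ("lever" %in% ch && meta$modality == "autonomous")
    st$lever <- simulate_lever(schedule, profile, seed, gr)
  if ("joystick" %in% ch && meta$modality == "self_drive")
    st$joystick_y <- simulate_joystick(schedule, profile, seed, gr,
                                       ns$joystick_base, ns$joystick_jitter)
  if ("meditation" %in% ch)
    st$meditation <- simulate_meditation(schedule, seed, gr, ns$meditation)
  if ("blink" %in% ch)
    st$blink_strength <- simulate_blinks(schedule, profile, exposure_index,
                                         seed)
  if ("eeg" %in% ch)
    st <- c(st, simulate_eeg(schedule, profile, exposure_index, seed,
                             noise_sd = ns$eeg))
  s <- session(meta, st, grid_rate = gr, check_channels = FALSE)
  attr(s, "schedule") <- schedule
  s
}

#' Simulate a cohort of sessions
#'
#' One session per participant x trial x loop. Participant profiles vary
#' mildly and deterministically around `profile`; the exposure index
#' increments across trials and loops to drive habituation. All randomness
#' derives from `config$seed`, so identical configurations give identical
#' cohorts.
#'
#' @param config a [sim_config()].
#' @param profile base [participant_profile()].
#' @param modality,condition session design cell to simulate.
#' @return list of [session()] objects, each carrying its ground-truth
#'   schedule as attribute `"schedule"`.
#' @export
simulate_cohort <- function(config, profile = participant_profile(),
                            modality = "autonomous", condition = "wide") {
  out <- list()
  restore_rng <- local_seed(derive_seed(config$seed, 31))
  on.exit(restore_rng(), add = TRUE)
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, 31, p))
    pp <- profile
    pp$scl_baseline <- profile$scl_baseline * stats::runif(1L, 0.8, 1.2)
    pp$scr_gain <- profile$scr_gain * stats::runif(1L, 0.85, 1.15)
    pp$ibi_baseline <- min(max(profile$ibi_baseline *
                                 stats::runif(1L, 0.9, 1.1), 0.5), 1.5)
    for (tr in seq_len(config$trials)) for (lp in seq_len(config$loops)) {
      k <- k + 1L
      sseed <- derive_seed(config$seed, p, tr, lp)
      sched <- make_schedule(config$duration, config$n_events,
                             config$min_gap, seed = sseed)
      meta <- session_meta(sprintf("P%02d", p), modality,
                           if (modality == "rest") "none" else condition,
                           trial = tr, loop = lp)
      expo <- (tr - 1L) * config$loops + (lp - 1L)
      out[[k]] <- simulate_session(meta, sched, pp, config,
                                   exposure_index = expo, seed = sseed)
    }
  }
  out
}
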