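test_that("schedules respect gaps, feasibility and determinism", {
  expect_equal(nrow(make_schedule(300, 0)$events), 0L)
  s1 <- make_schedule(300, 5, 10, seed = 3)
  s2 <- make_schedule(300, 5, 10, seed = 3)
  expect_identical(s1$events, s2$events)
  ev <- make_schedule(300, 5, min_gap = 10, seed = 8)$events
  gaps <- ev$onset[-1L] - (ev$onset + ev$duration)[-nrow(ev)]
  expect_true(all(gaps >= 10 - 1e-9))
  expect_true(all(ev$onset + ev$duration <= 300))
  expect_error(make_schedule(60, 10, min_gap = 10), "infeasible")
})

test_that("GSR simulation has tonic-only rest traces and delayed phasic peaks", {
  prof <- participant_profile()
  g0 <- simulate_gsr(empty_schedule(120), prof, seed = 2, noise_sd = 0)
  expect_equal(nrow(suppressWarnings(gsr_siginc(g0))$events), 0L)
  expect_lt(diff(range(g0$values)), 0.5)  # slow drift only

  # short impulse-like event: phasic peak lands in [onset+delay, +4 s]
  sched <- stressor_schedule(100, 1.5, 1, -1, 200)
  g1 <- simulate_gsr(sched, prof, seed = 2, noise_sd = 0)
  tonic <- simulate_gsr(empty_schedule(200), prof, seed = 2, noise_sd = 0)
  peak_t <- g1$timestamps[which.max(g1$values - tonic$values)]
  expect_gte(peak_t, 100 + prof$delays[["gsr"]])
  expect_lte(peak_t, 100 + prof$delays[["gsr"]] + 4)
})

test_that("habituation scales phasic amplitude by habituation_rate^exposure", {
  prof <- participant_profile(habituation_rate = 0.7)
  sched <- stressor_schedule(100, 6, 1, -1, 300)
  amp <- vapply(c(0, 3), function(e) {
    g <- simulate_gsr(sched, prof, exposure_index = e, seed = 5,
                      noise_sd = 0)
    tonic <- simulate_gsr(empty_schedule(300), prof, exposure_index = e,
                          seed = 5, noise_sd = 0)
    max(g$values - tonic$values)
  }, numeric(1))
  expect_equal(amp[2L] / amp[1L], 0.7^3, tolerance = 0.02)
})

test_that("IBI simulation produces physiological beats and LF/HF structure", {
  prof0 <- participant_profile(lf_amp = 0, hf_amp = 0, ibi_drop = 0)
  ibi <- simulate_ibi(empty_schedule(60), prof0, seed = 3, noise_sd = 0)
  expect_equal(ibi$values, rep(0.8, length(ibi$values)), tolerance = 1e-6)
  expect_error(
    simulate_ibi(empty_schedule(60),
                 participant_profile(ibi_baseline = 0.5, ibi_drop = 0.3),
                 seed = 1),
    "non-physiological")

  # a stressor raises median RRI starting about delays.heart after onset
  prof <- participant_profile(lf_amp = 0, hf_amp = 0)
  sched <- stressor_schedule(60, 8, 1, -1, 180)
  ibi2 <- simulate_ibi(sched, prof, seed = 4, noise_sd = 0)
  mr <- median_rri(ibi2)
  base <- 1 / 0.8
  rise_t <- mr$timestamps[which(mr$values > base * 1.02)[1L]]
  expect_gt(rise_t, 60 + prof$delays[["heart"]] - 3.5)
  expect_lt(rise_t, 60 + prof$delays[["heart"]] + 3.5)
})

test_that("EEG alpha asymmetry tracks the stressor state", {
  prof <- participant_profile(asymmetry_gain = 0.5)
  sched <- stressor_schedule(30, 60, 1, -1, 120)  # event covers half
  eeg <- simulate_eeg(sched, prof, seed = 6)
  t <- eeg$F3$timestamps
  instate <- t >= 30 & t < 90
  fs <- 256
  rp <- oracle_band_power(eeg$F4$values[instate], fs, c(8, 13))
  lp <- oracle_band_power(eeg$F3$values[instate], fs, c(8, 13))
  expect_gt(rp, lp)  # right alpha dominates during the stressor

  # zero asymmetry gain: characterization is near zero on average
  eeg0 <- simulate_eeg(sched, participant_profile(asymmetry_gain = 0),
                       seed = 6)
  asym <- alpha_asymmetry(eeg0, step_s = 1)
  expect_lt(abs(mean(asym$values)), 0.15 * sd(asym$values) +
              .Machine$double.eps)

  # different seeds: different noise, stable mean band power
  e1 <- simulate_eeg(empty_schedule(60), prof, seed = 1)
  e2 <- simulate_eeg(empty_schedule(60), prof, seed = 2)
  p1 <- oracle_band_power(e1$C3$values, fs, c(8, 13))
  p2 <- oracle_band_power(e2$C3$values, fs, c(8, 13))
  expect_false(identical(e1$C3$values, e2$C3$values))
  expect_equal(p1 / p2, 1, tolerance = 0.5)
})

test_that("blink strengths stay in range and counts follow the Poisson rate", {
  prof0 <- participant_profile(blink_base_rate = 0)
  b0 <- simulate_blinks(empty_schedule(60), prof0, seed = 1)
  expect_true(all(b0$values == 0))

  prof <- participant_profile(blink_base_rate = 0.2)
  b <- simulate_blinks(empty_schedule(600), prof, seed = 2)
  expect_true(all(b$values >= 0 & b$values <= 255))
  n_blinks <- length(detect_blink_events(b)$timestamps)
  # 120 expected; allow 4 sigma of Poisson spread (refractory trims a few)
  expect_gt(n_blinks, 120 - 4 * sqrt(120))
  expect_lt(n_blinks, 120 + 4 * sqrt(120))
})

test_that("the lever reproduces schedule onsets, plateaus and signs", {
  prof <- participant_profile()
  l0 <- simulate_lever(empty_schedule(60), prof, seed = 1)
  expect_true(all(l0$values == 0))
  sched <- stressor_schedule(20, 8, 0.8, -1, 60)
  l <- simulate_lever(sched, prof, seed = 1)
  mid <- l$values[l$timestamps > 22 & l$timestamps < 26]
  expect_equal(mid, rep(-0.8, length(mid)))
  onset_t <- l$timestamps[which(abs(l$values) > 0.01)[1L]]
  expect_equal(onset_t, 20, tolerance = 0.5)
})

test_that("joystick smoothness drops inside stressor windows", {
  prof <- participant_profile()
  sched <- make_schedule(300, 6, 10, seed = 9)
  jy <- simulate_joystick(sched, prof, seed = 9)
  r2 <- joystick_r2(jy)
  st <- state_on_grid(sched, r2$timestamps)
  expect_gt(mean(r2$values[st == 0]), 0.9)
  expect_lt(mean(r2$values[st == 1]), mean(r2$values[st == 0]) - 0.1)
  # zero jitter: R2 = 1 up to smoothing edge effects
  jy0 <- simulate_joystick(empty_schedule(120), prof, seed = 9,
                           base_sd = 0, jitter_gain = 0)
  expect_gt(min(joystick_r2(jy0)$values), 0.97)
})

test_that("cohorts are deterministic and respect the modality design", {
  cfg <- sim_config(2, 1, 1, seed = 21, duration = 60, n_events = 2,
                    channels = c("gsr", "ibi", "lever", "meditation"))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (s in c1) write_session(s, d1)
  for (s in c2) write_session(s, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # rest sessions carry no lever/joystick and an empty schedule
  rest <- simulate_session(session_meta("p", "rest", "none"),
                           make_schedule(60, 2, 5, seed = 1),
                           participant_profile(),
                           sim_config(1, 1, 1, seed = 1, duration = 60,
                                      channels = c("gsr", "ibi", "lever",
                                                   "joystick")),
                           seed = 1)
  expect_false(any(c("lever", "joystick_y") %in% names(rest$streams)))
  expect_equal(nrow(attr(rest, "schedule")$events), 0L)

  # meditation emulation: inverse smoothed arousal, anti-correlated with SCL
  cfgm <- sim_config(1, 1, 1, seed = 30, duration = 300,
                     channels = c("gsr", "ibi", "lever", "meditation"))
  s <- simulate_session(session_meta("p", "autonomous", "wide"),
                        make_schedule(300, 6, 10, seed = 30),
                        participant_profile(), cfgm, seed = 30)
  med <- meditation_series(s$streams$meditation)
  scl <- gsr_scl(s$streams$gsr)
  n <- min(length(med$values), length(scl$values))
  expect_lt(cor(med$values[1:n], scl$values[1:n], method = "spearman"), -0.2)
})
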