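test_that("running-mean smoothing preserves constants and ramps, kills Nyquist", {
  t <- seq(0, 10, by = 0.1)
  cst <- smooth_running_mean(sensor_stream("x", t, rep(3, length(t)), 10), 1)
  expect_true(all(cst$values == 3))
  ramp <- smooth_running_mean(sensor_stream("x", t, 2 * t, 10), 1)
  interior <- seq(11, length(t) - 10)
  expect_equal(ramp$values[interior], 2 * t[interior], tolerance = 1e-9)
  alt <- smooth_running_mean(sensor_stream("x", t,
                                           rep(c(1, -1), length.out =
                                                 length(t)), 10), 0.5)
  expect_lte(max(abs(alt$values[interior])), 0.2)
  expect_error(smooth_running_mean(sensor_stream("x", t, t, 10), 0.05),
               "2 samples")
})

test_that("slope-event detection finds injected responses and nothing on flat input", {
  t <- seq(0, 300, by = 0.1)
  flat <- sensor_stream("gsr", t, rep(5, length(t)), 10)
  expect_warning(out <- detect_sig_slope_increases(flat), "flat")
  expect_equal(nrow(out$events), 0L)

  prof <- participant_profile()
  onsets <- c(50, 150, 250)
  sched <- stressor_schedule(onsets, rep(6, 3), rep(1, 3), rep(-1, 3), 300)
  g <- simulate_gsr(sched, prof, seed = 13)
  sw <- gsr_siginc(g)
  expect_equal(nrow(sw$events), 3L)
  expect_equal(sw$events$onset, onsets + prof$delays[["gsr"]],
               tolerance = 1.5)

  # single step of height h: one event with height ~ h
  h <- 2
  step <- sensor_stream("gsr", t, 5 + h * (t >= 150), 10)
  sm <- smooth_running_mean(step, 1)
  ev <- detect_sig_slope_increases(sm)$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$height, 5 + h, tolerance = 0.05)
})

test_that("detection is shift invariant and scale equivariant", {
  sched <- stressor_schedule(c(40, 120), c(6, 8), c(1, 0.8), c(-1, -1), 200)
  g <- simulate_gsr(sched, participant_profile(), seed = 14)
  base <- gsr_siginc(g)
  shifted <- g; shifted$values <- g$values + 11
  sw_shift <- gsr_siginc(shifted)
  expect_equal(sw_shift$events$onset, base$events$onset)
  expect_equal(sw_shift$events$height, base$events$height + 11,
               tolerance = 1e-9)
  scaled <- g; scaled$values <- g$values * 3
  sw_scale <- gsr_siginc(scaled)
  expect_equal(sw_scale$events$onset, base$events$onset)
  expect_equal(sw_scale$events$height, base$events$height * 3,
               tolerance = 1e-9)
})

test_that("doubling the SCR gain doubles detected event heights above tonic", {
  sched <- stressor_schedule(c(50, 150), c(6, 7), c(1, 1), c(-1, -1), 250)
  p1 <- participant_profile(scr_gain = 1)
  p2 <- participant_profile(scr_gain = 2)
  g1 <- simulate_gsr(sched, p1, seed = 15, noise_sd = 0)
  g2 <- simulate_gsr(sched, p2, seed = 15, noise_sd = 0)
  h1 <- gsr_siginc(g1)$events$height - p1$scl_baseline
  h2 <- gsr_siginc(g2)$events$height - p2$scl_baseline
  expect_equal(h2 / h1, rep(2, length(h1)), tolerance = 0.1)
})

test_that("blink square waves appear in burst windows with bounded heights", {
  fs <- 128
  t <- seq(0, 120, by = 1 / fs)
  v <- numeric(length(t))
  burst <- runif(30, 60, 80)           # dense blinking inside [60, 80]
  sparse <- c(20, 40, 100)
  for (st in c(burst, sparse)) {
    ix <- which(t >= st & t < st + 0.1)
    v[ix] <- pmax(v[ix], 220)
  }
  bs <- sensor_stream("blink_strength", t, v, fs)
  sw <- blink_siginc(bs)
  expect_gt(nrow(sw$events), 0L)
  expect_true(all(sw$events$height <= 255))
  inburst <- sw$events$onset >= 59 & sw$events$onset <= 80
  expect_gt(sum(inburst), sum(!inburst))
  empty <- sensor_stream("blink_strength", t, numeric(length(t)), fs)
  expect_warning(out <- blink_siginc(empty), "flat")
  expect_equal(nrow(out$events), 0L)
})

test_that("median RRI is the reciprocal of the windowed median RR", {
  beats <- cumsum(rep(1, 60))
  ibi <- sensor_stream("ibi_event", beats[-1L], diff(beats), 0)
  mr <- median_rri(ibi)
  expect_true(all(abs(mr$values[!is.na(mr$values)] - 1) < 1e-9))
  # window {0.8, 1.0, 1.2} -> median 1.0 -> reciprocal 1.0
  ibi2 <- sensor_stream("ibi_event", c(1, 2, 3), c(0.8, 1.0, 1.2), 0)
  mr2 <- median_rri(ibi2, window_s = 5)
  expect_equal(mr2$values[mr2$timestamps == 2], 1.0)
})

test_that("alpha asymmetry is antisymmetric and scales with squared amplitude", {
  fs <- 256
  t <- seq(0, 20, by = 1 / fs)
  set.seed(31)
  mk <- function(a) sensor_stream("x", t,
    a * sin(2 * pi * 10 * t) + rnorm(length(t), 0, 0.01), fs)
  same <- lapply(setNames(nm = biostress:::EEG_CHANNELS),
                 function(nm) { s <- mk(5); s$name <- nm; s })
  asym0 <- alpha_asymmetry(same, step_s = 1)
  expect_lt(max(abs(asym0$values)), 0.05)

  eeg <- lapply(setNames(nm = biostress:::EEG_CHANNELS), function(nm) {
    s <- mk(if (nm %in% biostress:::EEG_RIGHT) 10 else 5)
    s$name <- nm
    s
  })
  asym <- alpha_asymmetry(eeg, step_s = 1)
  left_p <- oracle_band_power(eeg$F3$values, fs, c(8, 13))
  expect_equal(mean(asym$values) / left_p, 3, tolerance = 0.05)

  swapped <- eeg[c("F4", "FC4", "C4", "F3", "FC3", "C3")]
  names(swapped) <- biostress:::EEG_CHANNELS
  for (nm in names(swapped)) swapped[[nm]]$name <- nm
  asym_sw <- alpha_asymmetry(swapped, step_s = 1)
  expect_equal(asym_sw$values, -asym$values, tolerance = 1e-9)

  expect_error(alpha_asymmetry(eeg[-1L]), "F3")
})
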