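test_that("sensor_stream enforces its invariants", {
  expect_error(sensor_stream("x", c(0, 1), 1, 10), "equal length")
  expect_error(sensor_stream("x", c(0, 1, 1), c(1, 2, 3), 10),
               "strictly increasing")
  expect_error(sensor_stream("x", c(0, 1), c(1, Inf), 10), "non-finite")
  s <- sensor_stream("x", c(0, 1), c(1, NA), 10)
  expect_identical(length(s), 2L)
})

test_that("session metadata restricts modality/condition combinations", {
  expect_error(session_meta("p", "rest", "wide"), "condition 'none'")
  expect_error(session_meta("p", "autonomous", "none"), "wide")
  m <- session_meta("p", "autonomous", "narrow", trial = 2, loop = 3)
  expect_identical(m$trial, 2L)
})

test_that("write/read round-trip preserves names, lengths and values", {
  cfg <- sim_config(1, 1, 1, seed = 11, duration = 60,
                    channels = c("gsr", "ibi", "lever", "meditation",
                                 "blink"))
  sched <- make_schedule(60, 2, 5, seed = 11)
  s <- simulate_session(session_meta("p1", "autonomous", "wide"), sched,
                        participant_profile(), cfg, seed = 11)
  d <- withr::local_tempdir()
  manifest <- write_session(s, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  s2 <- read_session(d, s$meta)
  expect_setequal(names(s2$streams), names(s$streams))
  for (nm in names(s$streams)) {
    a <- s$streams[[nm]]; b <- s2$streams[[nm]]
    expect_identical(length(a), length(b))
    expect_equal(b$values, a$values, tolerance = 1e-9)
    expect_equal(b$timestamps, a$timestamps, tolerance = 1e-9)
  }
})

test_that("sessions with only EEG emit only the EEG file", {
  sched <- empty_schedule(10)
  eeg <- simulate_eeg(sched, participant_profile(), seed = 1)
  s <- session(session_meta("p2", "rest", "none"), eeg,
               check_channels = FALSE)
  d <- withr::local_tempdir()
  manifest <- write_session(s, d)
  expect_length(manifest, 1L)
  expect_match(names(manifest), "_eeg\\.csv$")
})

test_that("distinct metadata yields distinct file names", {
  m1 <- session_meta("p1", "autonomous", "wide", trial = 1)
  m2 <- session_meta("p1", "autonomous", "wide", trial = 2)
  expect_false(biostress:::session_stem(m1) == biostress:::session_stem(m2))
})

test_that("reading a session with a missing required channel errors", {
  cfg <- sim_config(1, 1, 1, seed = 12, duration = 30,
                    channels = c("ibi", "lever"))
  sched <- make_schedule(30, 1, 5, seed = 12)
  s <- simulate_session(session_meta("p3", "autonomous", "wide"), sched,
                        participant_profile(), cfg, seed = 12)
  d <- withr::local_tempdir()
  write_session(s, d)
  expect_error(read_session(d, s$meta), "gsr")
})

test_that("resample_to_grid handles hold, linear and bin_mean", {
  cst <- sensor_stream("c", seq(0, 5, by = 0.25), rep(7, 21), 4)
  for (m in c("hold", "linear"))
    expect_true(all(resample_to_grid(cst, 10, m)$values == 7))
  # bin_mean: occupied bins constant, unoccupied bins missing-flagged
  bm <- resample_to_grid(cst, 10, "bin_mean")$values
  expect_true(all(bm[!is.na(bm)] == 7))
  expect_true(all(resample_to_grid(cst, 2, "bin_mean")$values == 7))
  # a linear ramp is preserved by linear resampling
  t <- seq(0, 1, by = 1 / 256)
  ramp <- sensor_stream("r", t, 3 * t, 256)
  out <- resample_to_grid(ramp, 10, "linear")
  expect_equal(out$values, 3 * out$timestamps, tolerance = 1e-9)
  # hold at the native rate is the identity
  out2 <- resample_to_grid(ramp, 256, "hold")
  expect_equal(out2$values, ramp$values, tolerance = 1e-12)
  # event series bin_mean: events land in their bins, other bins missing
  ev <- sensor_stream("e", c(1.0, 2.0), c(0.9, 1.1), 0)
  out3 <- resample_to_grid(ev, 10, "bin_mean")
  hit <- which(!is.na(out3$values))
  expect_equal(out3$values[hit], c(0.9, 1.1))
  expect_equal(out3$timestamps[hit], c(1.0, 2.0), tolerance = 1e-9)
  expect_error(resample_to_grid(sensor_stream("e", 1, 1, 0), 10, "linear"),
               "2 events")
})

test_that("alignment shifts offset channels onto the common clock", {
  t <- seq(0, 30, by = 0.1)
  base <- sin(2 * pi * t / 7)
  lever <- sensor_stream("lever", t, base, 10)
  gsr <- sensor_stream("gsr", t, base, 10)
  ibi <- sensor_stream("ibi_event", seq(0.8, 29.8, by = 0.8),
                       rep(0.8, 37), 0)
  meta0 <- session_meta("p", "autonomous", "wide")
  s0 <- session(meta0, list(gsr = gsr, lever = lever, ibi_event = ibi))
  a0 <- align_streams(s0)
  expect_equal(a0$streams$lever$timestamps, t)

  # +0.5 s offset on the lever moves its events 0.5 s earlier
  meta1 <- session_meta("p", "autonomous", "wide",
                        clock_offsets = c(lever = 0.5))
  s1 <- session(meta1, list(gsr = gsr, lever = lever, ibi_event = ibi))
  a1 <- align_streams(s1)
  expect_equal(a1$streams$lever$timestamps[1L], t[1L] - 0.5)
  expect_error(align_streams(session(session_meta("p", "autonomous", "wide",
    clock_offsets = c(lever = 1000)),
    list(gsr = gsr, lever = lever, ibi_event = ibi))), "duration")
})

test_that("a known injected skew is corrected back to zero lag", {
  t <- seq(0, 60, by = 0.1)
  set.seed(42)
  x <- as.numeric(stats::filter(rnorm(length(t)), rep(1, 15) / 15,
                                sides = 2))
  x[is.na(x)] <- 0
  a <- sensor_stream("gsr", t, x, 10)
  # duplicate channel recorded on a device whose clock runs 1 s ahead
  b <- sensor_stream("lever", t + 1.0, x, 10)
  ibi <- sensor_stream("ibi_event", seq(0.8, 59, by = 0.8),
                       rep(0.8, 73), 0)
  meta <- session_meta("p", "autonomous", "wide",
                       clock_offsets = c(lever = 1.0))
  al <- align_streams(session(meta, list(gsr = a, lever = b,
                                         ibi_event = ibi)))
  expect_equal(al$streams$lever$timestamps, al$streams$gsr$timestamps,
               tolerance = 1e-9)
  pa <- parameter_series("GSRsiginc", al$streams$gsr$timestamps,
                         al$streams$gsr$values)
  pb <- parameter_series("Lever", al$streams$lever$timestamps,
                         al$streams$lever$values)
  d <- estimate_delay(pa, pb, max_lag_s = 5)
  expect_equal(d$lag_s, 0, tolerance = 1e-9)
})
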