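make_tone <- function(freq, amp = 10, dur = 20, fs = 256, noise = 0) {
  t <- seq(0, dur, by = 1 / fs)
  set.seed(61)
  sensor_stream("F3", t, amp * sin(2 * pi * freq * t) +
                  rnorm(length(t), 0, noise), fs, "uV")
}

test_that("the 8-25 Hz band-pass is selective and masks artifacts", {
  tone10 <- make_tone(10)
  out10 <- eeg_bandpass(tone10)
  gain10 <- sd(out10$values, na.rm = TRUE) / sd(tone10$values)
  expect_gte(gain10, 0.95)

  tone2 <- make_tone(2)
  out2 <- eeg_bandpass(tone2)
  gain2 <- sd(out2$values, na.rm = TRUE) / sd(tone2$values)
  expect_lt(20 * log10(gain2), -20)

  spiky <- make_tone(10, amp = 150)
  expect_true(anyNA(eeg_bandpass(spiky)$values))

  # zero phase: the filtered tone peaks where the input peaks
  ccf_peak <- which.max(ccf(out10$values, tone10$values, lag.max = 20,
                            plot = FALSE)$acf) - 21L
  expect_equal(ccf_peak, 0L)
})

test_that("spectrograms hit 0.1 Hz bins and satisfy Parseval", {
  tone <- make_tone(10, dur = 30)
  sp <- spectrogram_01hz(eeg_bandpass(tone))
  expect_equal(diff(sp$freqs)[1L], 0.1, tolerance = 1e-9)
  peak_freq <- sp$freqs[which.max(sp$power[1L, ])]
  expect_equal(peak_freq, 10, tolerance = 0.05)

  # band power of the implementation matches the direct-DFT oracle
  w <- biostress:::hamming_window(2560)
  seg <- tone$values[1:2560]
  orc <- oracle_band_power(seg, 256, c(9.5, 10.55), w, nfft = 2560)
  got <- sum(sp$power[1L, sp$freqs >= 9.5 & sp$freqs < 10.55]) * 0.1
  # note: spectrogram windows are bandpassed first; compare on raw tone
  sp_raw <- spectrogram_01hz(tone)
  got_raw <- sum(sp_raw$power[1L, sp_raw$freqs >= 9.5 &
                                sp_raw$freqs < 10.55]) * 0.1
  expect_equal(got_raw, orc, tolerance = 0.01 * orc)

  # Parseval: integrated PSD ~ variance of the (tapered) window
  total <- sum(sp_raw$power[1L, ]) * 0.1
  expect_equal(total, var(seg) * 2560 / 2561, tolerance = 0.05 * total)

  # quadratic amplitude scaling
  sp2 <- spectrogram_01hz(make_tone(10, amp = 20, dur = 30))
  expect_equal(max(sp2$power[1L, ]) / max(sp_raw$power[1L, ]), 4,
               tolerance = 0.01)

  # silence gives a ~zero matrix
  silent <- sensor_stream("F3", seq(0, 15, by = 1 / 256),
                          numeric(3841), 256, "uV")
  expect_lt(max(spectrogram_01hz(silent)$power), 1e-20)
})

test_that("band condensation yields means, slopes and variances per band", {
  tone <- make_tone(10, dur = 30, noise = 0.5)
  bs <- condense_bands(spectrogram_01hz(tone))
  expect_gt(mean(bs$alpha1$series), 100 * mean(bs$beta$series))

  # linearly growing alpha amplitude: positive alpha1 slope
  fs <- 256
  t <- seq(0, 60, by = 1 / fs)
  grow <- sensor_stream("F3", t, (1 + t / 60) * 5 * sin(2 * pi * 10 * t),
                        fs, "uV")
  bs2 <- condense_bands(spectrogram_01hz(grow))
  expect_gt(bs2$alpha1$slope, 0)

  # flat (white-ish) spectrum: all bands about equal
  set.seed(62)
  wn <- sensor_stream("F3", t, rnorm(length(t)), fs, "uV")
  bs3 <- condense_bands(spectrogram_01hz(wn))
  expect_equal(mean(bs3$alpha1$series) / mean(bs3$beta$series), 1,
               tolerance = 0.2)
})

test_that("variance z-score counting matches hand computation", {
  mk <- function(vs) {
    do.call(rbind, lapply(seq_along(vs), function(i)
      expand.grid(condition = "narrow", band = "alpha1",
                  channel = biostress:::EEG_CHANNELS,
                  dataset = paste0("d", i), variance = vs[i],
                  stringsAsFactors = FALSE)))
  }
  # one channel gets an outlying variance in one dataset
  vdf <- mk(c(1, 1, 1, 1, 1, 1))
  vdf$variance[vdf$channel == "F4" & vdf$dataset == "d6"] <- 12
  v <- c(1, 1, 1, 1, 1, 12)
  z6 <- abs((12 - mean(v)) / sd(v))    # = 2.041..., crosses the |z| >= 2 rule
  expect_gt(z6, 2)
  tab <- suppressWarnings(variance_count_table(vdf, z_rule = "ge2"))
  expect_equal(tab$F4, 1L)
  tab_lt <- suppressWarnings(variance_count_table(vdf, z_rule = "lt2"))
  expect_equal(tab_lt$F4, 5L)

  # all-equal variances: degenerate, zero counts with warnings
  w <- testthat::capture_warnings(
    tab0 <- variance_count_table(mk(rep(2, 4))))
  expect_match(w, "zero variance spread", all = TRUE)
  expect_true(all(as.matrix(tab0[, biostress:::EEG_CHANNELS]) == 0))

  # permutation invariance across datasets
  vdf2 <- vdf[sample(nrow(vdf)), ]
  tab2 <- suppressWarnings(variance_count_table(vdf2, z_rule = "ge2"))
  expect_equal(tab2$F4, tab$F4)
  expect_error(variance_count_table(mk(c(1, 2))), "at least 3")
})

test_that("hemisphere summary flags the dominant side", {
  tab <- data.frame(condition = "narrow", band = "alpha1",
                    F3 = 5, FC3 = 9, C3 = 6, F4 = 3, FC4 = 5, C4 = 2)
  s <- hemisphere_pattern_summary(tab)
  expect_equal(s$left, 20)
  expect_equal(s$right, 10)
  expect_equal(s$dominance, "left")
  tab0 <- data.frame(condition = "wide", band = "beta",
                     F3 = 0, FC3 = 0, C3 = 0, F4 = 0, FC4 = 0, C4 = 0)
  expect_equal(hemisphere_pattern_summary(tab0)$dominance, "none")
  sym <- data.frame(condition = "wide", band = "alpha2",
                    F3 = 2, FC3 = 3, C3 = 1, F4 = 2, FC4 = 3, C4 = 1)
  expect_equal(hemisphere_pattern_summary(sym)$dominance, "none")
})

test_that("deeper amplitude modulation yields larger alpha band variance", {
  # mechanism behind hemispheric variance asymmetry: the hemisphere whose
  # alpha swings harder with the stressor state shows more band variance
  fs <- 256
  t <- seq(0, 120, by = 1 / fs)
  state <- as.numeric(t %% 30 < 10)
  mk_mod <- function(depth) {
    set.seed(63)
    sensor_stream("F3", t,
                  5 * (1 - depth * state) * sin(2 * pi * 10 * t) +
                    rnorm(length(t), 0, 0.5), fs, "uV")
  }
  v_deep <- condense_bands(spectrogram_01hz(mk_mod(0.5)))$alpha1$variance
  v_shal <- condense_bands(spectrogram_01hz(mk_mod(0.1)))$alpha1$variance
  expect_gt(v_deep, 2 * v_shal)
})
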