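# Morlet spectrograms, Welch PSDs, onset-triggered averages, band power.

test_that("Morlet spectrogram localizes tones and respects its contracts", {
  fs <- 500
  tt <- (0:(4 * fs - 1)) / fs
  x <- cos(2 * pi * 40 * tt)
  sp <- morlet_spectrogram(x, fs, freqs = 2:150)
  ridge <- sp$freqs[which.max(rowMeans(sp$power))]
  expect_equal(ridge, 40)
  # unit-amplitude tone -> ridge power ~ 1, constant in time inside the COI
  in_coi <- sp$coi[sp$freqs == 40, ]
  ridge_t <- sp$power[sp$freqs == 40, in_coi]
  expect_equal(mean(ridge_t), 1, tolerance = 0.05)
  expect_lt(sd(ridge_t) / mean(ridge_t), 0.02)
  # all-zero trace -> all-zero power
  expect_equal(max(morlet_spectrogram(numeric(1000), fs, freqs = c(10, 40))$power), 0)
  expect_error_class(morlet_spectrogram(x, fs, freqs = c(10, 300)), "spec_error")
})

test_that("two tones give two ridges without cross-terms above -20 dB", {
  fs <- 500
  tt <- (0:(6 * fs - 1)) / fs
  x <- cos(2 * pi * 8 * tt) + cos(2 * pi * 80 * tt)
  sp <- morlet_spectrogram(x, fs, freqs = 2:120)
  coi_all <- apply(sp$coi, 1, all)
  pw <- rowMeans(sp$power[, apply(sp$coi, 2, all), drop = FALSE])
  expect_equal(sp$freqs[order(pw, decreasing = TRUE)[1:2]] %in% c(8, 80),
               c(TRUE, TRUE))
  # midway frequency (e.g. 40 Hz) at least 20 dB below the ridges
  expect_lt(pw[sp$freqs == 40], 0.01 * min(pw[sp$freqs == 8], pw[sp$freqs == 80]))
})

test_that("spectrogram is time-shift equivariant", {
  fs <- 500
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(3000), rep(1, 5), sides = 2))
  x[is.na(x)] <- 0
  shift <- 200L
  sp1 <- morlet_spectrogram(x, fs, freqs = c(10, 20, 40))
  sp2 <- morlet_spectrogram(c(numeric(shift), x[1:(length(x) - shift)]),
                            fs, freqs = c(10, 20, 40))
  sel <- 1000:1800
  expect_equal(sp2$power[, sel + shift], sp1$power[, sel], tolerance = 1e-6)
})

test_that("Welch PSD satisfies Parseval and resolves tones", {
  fs <- 1000
  set.seed(6)
  x <- rnorm(20000)
  ps <- welch_psd(x, fs, nfft = 4096)
  expect_equal(sum(ps$psd) * ps$df, var(x), tolerance = 0.05)
  tone <- sin(2 * pi * 100 * (0:19999) / fs)
  pt <- welch_psd(tone, fs, nfft = 4096)
  expect_equal(pt$freq[which.max(pt$psd)], 100, tolerance = fs / 4096)
  expect_error_class(welch_psd(rnorm(1000), fs, nfft = 4096), "length_error")
})

test_that("triggered averages align to onsets and average trials", {
  fs <- 500
  ss <- fixture_session()
  trace <- ss$truth$s[1, ]
  ev <- ss$events
  tp <- triggered_power(trace, fs, events = ev, freqs = seq(5, 120, by = 5))
  expect_equal(range(tp$time_ms), c(-1000, 500))
  expect_equal(tp$n_trials, length(ev$pull_onsets))
  # list-of-spectrograms form: identical trials average to themselves
  s1 <- morlet_spectrogram(trace[1:1000], fs, freqs = c(10, 40))
  avg <- triggered_power(list(s1, s1, s1))
  expect_equal(avg$power, s1$power)
})

test_that("state-dependent gamma dynamics appear in triggered band power", {
  fs <- 500
  ss <- fixture_session()
  # source 1: fast gamma pull-enhanced -> post-onset fast power > pre-onset
  tp1 <- triggered_power(ss$truth$s[1, ], fs, events = ss$events,
                         freqs = seq(20, 120, by = 2))
  bp_fast <- band_power(tp1, c(60, 120), probe_hz = 80)
  pre <- mean(bp_fast$power[tp1$time_ms >= -1000 & tp1$time_ms <= -500])
  post <- mean(bp_fast$power[tp1$time_ms >= -100 & tp1$time_ms <= 300])
  expect_gt(post, 2 * pre)
  # source 2: slow gamma rises ~100 ms after onset
  tp2 <- triggered_power(ss$truth$s[2, ], fs, events = ss$events,
                         freqs = seq(20, 120, by = 2))
  bp_slow <- band_power(tp2, c(20, 50))
  hold <- mean(bp_slow$power[tp2$time_ms >= -1000 & tp2$time_ms <= -500])
  late <- mean(bp_slow$power[tp2$time_ms >= 150 & tp2$time_ms <= 400])
  expect_gt(late, hold)
  # and the early pull window has not yet risen as much as the delayed window
  early <- mean(bp_slow$power[tp2$time_ms >= -100 & tp2$time_ms <= 50])
  expect_gt(late, early)
  # source 1 shows no such post-onset slow-gamma increase
  bp1_slow <- band_power(tp1, c(20, 50))
  late1 <- mean(bp1_slow$power[tp1$time_ms >= 150 & tp1$time_ms <= 400])
  hold1 <- mean(bp1_slow$power[tp1$time_ms >= -1000 & tp1$time_ms <= -500])
  expect_lt(late1, hold1)
})

test_that("band_power picks the in-band maximum or the probe frequency", {
  fs <- 500
  tt <- (0:(3 * fs - 1)) / fs
  sp <- morlet_spectrogram(cos(2 * pi * 35 * tt), fs, freqs = 20:50)
  bp <- band_power(sp, c(20, 50))
  expect_equal(bp$peak_freq, 35)
  spp <- morlet_spectrogram(cos(2 * pi * 35 * tt), fs, freqs = 60:120)
  bpp <- band_power(spp, c(60, 120), probe_hz = 80)
  expect_equal(bpp$peak_freq, 80)
  expect_error_class(band_power(sp, c(200, 300)), "spec_error")
})

test_that("hold/pull state gains are recovered from triggered band power", {
  # generator round-trip: 2:1 hold:pull slow-gamma power gain recovered
  # within 15% from the wavelet band-power ratio
  fs <- 500
  onsets <- seq(3, 75, by = 4)
  ev <- event_table(onsets)
  sp <- list(source_spec("nonreversing_superficial",
                         band_powers = c(theta = 0, slow_gamma = 0.5, fast_gamma = 0),
                         state_gains = list(theta = c(hold = 1, pull = 1),
                                            slow_gamma = c(hold = 1, pull = 0.5),
                                            fast_gamma = c(hold = 1, pull = 1)),
                         evoked = c(amp = 0, peak_ms = 0, width_ms = 150, biphasic = 0)))
  s <- make_timecourses(sp, ev, fs, 77, seed = 12)
  tp <- triggered_power(s[1, ], fs, events = ev, freqs = seq(20, 50, by = 2))
  bp <- band_power(tp, c(20, 50))
  hold <- mean(bp$power[tp$time_ms >= -1000 & tp$time_ms <= -500])
  pull <- mean(bp$power[tp$time_ms >= -100 & tp$time_ms <= 250])
  expect_equal(hold / pull, 2, tolerance = 0.15)
})
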