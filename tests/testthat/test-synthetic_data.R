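# Ground-truth generator: loading archetypes, time-course statistics,
# mixing, phase-locked spikes, and the lever trajectory.

test_that("loading archetypes have the documented depth geometry", {
  V <- make_loadings(default_source_specs(), default_depths())
  expect_equal(dim(V), c(8L, 4L))
  expect_equal(unname(apply(abs(V), 2, max)), rep(1, 4))
  # volume-conducted column is exactly affine: zero second difference
  expect_equal(diff(diff(V[, 4])), rep(0, 6), tolerance = 1e-12)
  # both reversing profiles cross zero exactly once, at 1000 um: channels
  # above the reversal share one sign, channels below share the other, and
  # the profile vanishes at the reversal depth itself (a grid point here)
  x <- default_depths()
  for (cc in 2:3) {
    v <- V[, cc]
    expect_lt(abs(v[x == 1000]), 1e-10)
    expect_true(all(v[x < 1000] * v[x < 1000][1] > 0))
    expect_true(all(v[x > 1000] * v[x > 1000][1] > 0))
    expect_lt(v[x < 1000][1] * v[x > 1000][1], 0)
  }
  # nonreversing source peaks at the depth nearest 700 um, no sign change
  expect_equal(which.max(V[, 1]), which.min(abs(default_depths() - 700)))
  expect_true(all(V[, 1] > 0))
  expect_error_class(make_loadings(default_source_specs(), c(100, 250)), "spec_error")
  expect_error_class(source_spec("spiral"), "spec_error")
})

test_that("time courses are deterministic under a fixed seed and band-limited", {
  ev <- event_table(c(2, 5, 8))
  s1 <- make_timecourses(default_source_specs(), ev, 500, 10, seed = 42)
  s2 <- make_timecourses(default_source_specs(), ev, 500, 10, seed = 42)
  expect_identical(s1, s2)
  s3 <- make_timecourses(default_source_specs(), ev, 500, 10, seed = 43)
  expect_false(identical(s1, s3))
  expect_error_class(make_timecourses(default_source_specs(), ev, 200, 10),
                     "aliasing_error")
  expect_error_class(make_timecourses(default_source_specs(), ev, 500, 5),
                     "validation_error")
})

test_that("hold/pull state gains shape band power as specified", {
  # hold:pull slow-gamma gain 2:1 -> hold-window power exceeds pull-window
  # power in every trial (oracle: direct band power on the generated source)
  fs <- 500
  onsets <- seq(3, 39, by = 4)
  ev <- event_table(onsets)
  sp <- list(source_spec("nonreversing_superficial",
                         band_powers = c(theta = 0, slow_gamma = 0.5, fast_gamma = 0),
                         state_gains = list(theta = c(hold = 1, pull = 1),
                                            slow_gamma = c(hold = 1, pull = 0.5),
                                            fast_gamma = c(hold = 1, pull = 1)),
                         evoked = c(amp = 0, peak_ms = 0, width_ms = 150, biphasic = 0)))
  s <- make_timecourses(sp, ev, fs, 41, seed = 9)
  x <- bandpass(s[1, ], fs, c(20, 50))
  hold_p <- pull_p <- numeric(length(onsets))
  for (i in seq_along(onsets)) {
    hi <- round((onsets[i] - 1.0) * fs):round((onsets[i] - 0.5) * fs)
    pi_ <- round((onsets[i] - 0.2) * fs):round((onsets[i] + 0.3) * fs)
    hold_p[i] <- mean(x[hi]^2); pull_p[i] <- mean(x[pi_]^2)
  }
  # hold power dominates in (nearly) every trial; short pull windows make
  # single-trial power estimates noisy, so allow one exception
  expect_gte(mean(hold_p > pull_p), 0.9)
  # and the mean ratio recovers the 2:1 power gain within 15%
  expect_equal(mean(hold_p) / mean(pull_p), 2, tolerance = 0.15)
})

test_that("mix is an exact linear mixture at zero noise", {
  ev <- event_table(2)
  sp <- default_source_specs()
  V <- make_loadings(sp)
  s <- make_timecourses(sp, ev, 500, 4, seed = 1)
  rec <- mix(V, s, noise_sd = 0)
  expect_equal(rec$samples, V %*% s, ignore_attr = TRUE)
  # rank-1: single source mixes to proportional channels
  rec1 <- mix(V[, 1, drop = FALSE], s[1, , drop = FALSE], noise_sd = 0,
              depths = default_depths(), fs = 500)
  expect_equal(qr(rec1$samples)$rank, 1L)
  expect_error_class(mix(V, s, noise_sd = -1), "spec_error")
})

test_that("spike generator hits its phase-locking targets", {
  fs <- 500; dur <- 650
  ev <- event_table(seq(5, dur - 5, by = 10))
  sp <- list(source_spec("nonreversing_superficial",
                         band_powers = c(theta = 0, slow_gamma = 0.5, fast_gamma = 0),
                         evoked = c(amp = 0, peak_ms = 0, width_ms = 150, biphasic = 0)))
  s <- make_timecourses(sp, ev, fs, dur, seed = 5)
  # homogeneous Poisson at plv 0: no detectable locking
  st0 <- make_spikes(s[1, ], fs, c(20, 50), plv_target = 0, rate = 6, seed = 3)
  ph0 <- spike_phases(st0$units[[1]]$times, s[1, ], fs, c(20, 50))
  expect_gt(rayleigh(ph0)$p, 1e-3)
  expect_lt(plv(ph0), 0.06)
  # degenerate limit: spikes only at the preferred phase
  st1 <- make_spikes(s[1, ], fs, c(20, 50), plv_target = 1, rate = 6,
                     preferred_phase = pi / 3, seed = 3)
  ph1 <- spike_phases(st1$units[[1]]$times, s[1, ], fs, c(20, 50))
  expect_gt(plv(ph1), 0.97)
  # mid-range target recovered within +/- 0.05 at > 3000 spikes
  st5 <- make_spikes(s[1, ], fs, c(20, 50), plv_target = 0.5, rate = 6, seed = 3)
  ph5 <- spike_phases(st5$units[[1]]$times, s[1, ], fs, c(20, 50))
  expect_gt(length(ph5), 3000)
  expect_equal(plv(ph5), 0.5, tolerance = 0.05)
  expect_error_class(make_spikes(s[1, ], fs, c(20, 50), plv_target = 1.2), "spec_error")
  expect_error_class(make_spikes(s[1, ], fs, c(20, 50), rate = 0), "spec_error")
})

test_that("lever trajectories are hold-then-pull with parameterized jitter", {
  fs <- 200
  ev <- event_table(c(2, 5, 8, 11, 14, 17))
  lv <- make_lever(ev, fs, jitter = 0)
  # one excursion per event, all identical under zero jitter
  seg <- function(on) lv[(round(on * fs) + 1):(round(on * fs) + fs)]
  segs <- vapply(ev$pull_onsets[1:5], seg, numeric(fs))
  expect_true(all(apply(segs, 1, function(r) diff(range(r)) < 1e-12)))
  expect_equal(max(lv), 1)
  # hold level before each onset
  for (on in ev$pull_onsets)
    expect_equal(lv[round((on - 0.5) * fs)], 0)
  # 18 events -> 18 excursions (count connected supra-half-max runs)
  ev18 <- event_table(seq(2, 2 + 17 * 3, by = 3))
  lv18 <- make_lever(ev18, fs, jitter = 0.05, seed = 2)
  runs <- rle(lv18 > 0.5)
  expect_equal(sum(runs$values), 18L)
  # a pull without 1 s of preceding hold is rejected
  expect_error_class(make_lever(event_table(c(2, 2.8)), fs), "spec_error")
})

test_that("whole sessions are reproducible and internally consistent", {
  a <- synth_session(n_trials = 4, fs = 500, seed = 99)
  b <- synth_session(n_trials = 4, fs = 500, seed = 99)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$spikes$units[[1]]$times, b$spikes$units[[1]]$times)
  expect_equal(ncol(a$truth$s), ncol(a$recording$samples))
  dir <- withr::local_tempdir()
  write_session(a, dir)
  expect_true(all(file.exists(file.path(dir,
    c("recording.bin", "recording.json", "events.tsv", "lever.tsv",
      "spikes.tsv", "ground_truth.json")))))
  back <- read_recording(file.path(dir, "recording.bin"))
  expect_equal(back$samples, a$recording$samples, tolerance = 1e-6)
})
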