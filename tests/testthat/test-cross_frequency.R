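# Filtering, analytic signal, phase-amplitude distributions, Tort MI,
# surrogate significance, Watson-Williams.

test_that("the theta band-pass passes 8 Hz and rejects 80 Hz", {
  fs <- 1000
  tt <- (0:(10 * fs - 1)) / fs
  inside <- bandpass(cos(2 * pi * 8 * tt), fs, c(4, 10))
  sel <- 2000:8000
  expect_equal(sd(inside[sel]) * sqrt(2), 1, tolerance = 0.05)
  outside <- bandpass(cos(2 * pi * 80 * tt), fs, c(4, 10))
  atten_db <- 20 * log10(sd(outside[sel]) * sqrt(2))
  expect_lt(atten_db, -40)
  expect_error_class(bandpass(tt, fs, c(0, 10)), "spec_error")
  expect_error_class(bandpass(tt, fs, c(400, 600)), "spec_error")
})

test_that("analytic phase advances at the tone frequency and envelopes recover AM", {
  fs <- 500
  tt <- (0:(6 * fs - 1)) / fs
  x <- cos(2 * pi * 8 * tt)
  pa <- analytic_phase_amp(x)
  expect_false(pa$degenerate)
  sel <- 500:2500
  dph <- diff(pa$phase[sel]) %% (2 * pi)
  expect_equal(mean(dph), 2 * pi * 8 / fs, tolerance = 1e-3)
  expect_equal(mean(pa$amplitude[sel]), 1, tolerance = 0.01)
  # known modulator recovered from the envelope
  mod <- 1 + 0.5 * cos(2 * pi * 1.5 * tt)
  am <- analytic_phase_amp(mod * cos(2 * pi * 40 * tt))
  expect_gt(cor(am$amplitude[sel], mod[sel]), 0.99)
  z <- analytic_phase_amp(numeric(100))
  expect_true(z$degenerate)
  expect_true(all(is.na(z$phase)))
})

test_that("theta reference is the raw channel with highest theta power", {
  ss <- fixture_session()
  ref <- theta_reference(ss$recording)
  # the volume-conducted source carries the additive theta; its loading is
  # maximal at the deepest electrode
  expect_equal(ref$channel, which.max(abs(ss$truth$V[, 4])))
})

test_that("phase-amplitude distributions normalize and match closed forms", {
  set.seed(3)
  ph <- runif(40000, -pi, pi)
  # constant envelope: uniform bins
  b0 <- phase_amp_distribution(ph, rep(2, length(ph)))
  expect_equal(sum(b0), 1, tolerance = 1e-9)
  expect_equal(as.numeric(b0), rep(1 / 18, 18), tolerance = 0.01)
  # raised-cosine envelope peaking at 10 degrees (a bin center, so the
  # preferred bin is unique): bin means follow the analytic bin average
  phi0 <- pi / 18
  env <- 1 + cos(ph - phi0)
  b1 <- phase_amp_distribution(ph, env)
  edges <- seq(0, 2 * pi, length.out = 19)
  exact <- 1 + (sin(edges[-1] - phi0) - sin(edges[-19] - phi0)) / diff(edges)
  exact <- exact / sum(exact)
  expect_equal(as.numeric(b1), exact, tolerance = 0.02)
  expect_equal(attr(b1, "bin_centers_deg")[which.max(b1)], 10)
  expect_error_class(phase_amp_distribution(ph, env[-1]), "validation_error")
})

test_that("modulation index is the normalized KL divergence from uniform", {
  expect_equal(modulation_index(rep(1 / 18, 18)), 0, tolerance = 1e-12)
  expect_equal(modulation_index(c(1, rep(0, 17))), 1)
  # independent entropy oracle on raised-cosine bins
  edges <- seq(0, 2 * pi, length.out = 19)
  bins <- 1 + (sin(edges[-1]) - sin(edges[-19])) / diff(edges)
  bins <- bins / sum(bins)
  H <- -sum(bins * log(bins))
  expect_equal(modulation_index(bins), (log(18) - H) / log(18), tolerance = 1e-12)
  # invariant to envelope scaling
  set.seed(9)
  ph <- runif(20000, -pi, pi); env <- 1 + cos(ph)
  expect_equal(coupling_mi(ph, env)$mi, coupling_mi(ph, 7 * env)$mi,
               tolerance = 1e-12)
  expect_error_class(modulation_index(c(-0.1, rep(1.1 / 17, 17))), "spec_error")
})

test_that("measured MI increases monotonically with the generator coupling depth", {
  fs <- 500
  ev <- event_table(seq(5, 55, by = 5))
  mis <- vapply(c(0, 0.3, 0.6, 0.9), function(kc) {
    sp <- list(source_spec("nonreversing_superficial",
                           band_powers = c(theta = 0, slow_gamma = 0.5, fast_gamma = 0),
                           coupling_depth = kc,
                           evoked = c(amp = 0, peak_ms = 0, width_ms = 150, biphasic = 0)))
    s <- make_timecourses(sp, ev, fs, 62, seed = 5)
    env <- analytic_phase_amp(bandpass(s[1, ], fs, c(20, 50)))$amplitude
    coupling_mi(attr(s, "theta_phase"), env)$mi
  }, numeric(1))
  expect_true(!is.unsorted(mis))
  expect_gt(mis[4], 10 * max(mis[1], 1e-6))
})

test_that("surrogate test is calibrated at zero coupling and powerful at strong coupling", {
  fs <- 500
  mk_trials <- function(kc, seed, n_tr = 20) {
    ev <- event_table(seq(3, 3 + (n_tr - 1) * 2, by = 2))
    sp <- list(source_spec("nonreversing_superficial",
                           band_powers = c(theta = 0, slow_gamma = 0.4, fast_gamma = 0),
                           coupling_depth = kc,
                           evoked = c(amp = 0, peak_ms = 0, width_ms = 150, biphasic = 0)))
    s <- make_timecourses(sp, ev, fs, 3 + n_tr * 2, seed = seed)
    th <- attr(s, "theta_phase")
    env <- analytic_phase_amp(bandpass(s[1, ], fs, c(20, 50)))$amplitude
    idx <- lapply(ev$pull_onsets, function(on)
      round((on - 1) * fs):round((on + 0.5) * fs))
    list(ph = lapply(idx, function(i) th[i]), env = lapply(idx, function(i) env[i]))
  }
  # null: false-positive fraction near the nominal 1% (50 seeds, binomial slack)
  hits <- vapply(1:50, function(sd) {
    tr <- mk_trials(0, sd)
    surrogate_mi(tr$ph, tr$env, n_surr = 200, seed = sd + 1000)$significant
  }, logical(1))
  expect_lte(sum(hits), 4)
  # power: strong coupling detected in at least 9/10 seeds
  hits9 <- vapply(1:10, function(sd) {
    tr <- mk_trials(0.9, sd)
    surrogate_mi(tr$ph, tr$env, n_surr = 200, seed = sd + 2000)$significant
  }, logical(1))
  expect_gte(sum(hits9), 9)
  tr <- mk_trials(0.9, 1)
  expect_error_class(surrogate_mi(tr$ph[1], tr$env[1]), "insufficient_trials_error")
})

test_that("Watson-Williams detects separated circular means at its nominal level", {
  rvm <- function(n, mu, kappa) {
    # Best-Fisher von Mises sampler
    a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n); i <- 0
    while (i < n) {
      u <- runif(3)
      z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[3]) + 1 - c0 >= 0) {
        i <- i + 1
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      }
    }
    out
  }
  set.seed(11)
  # identical duplicated groups: F ~ 0
  g <- rvm(100, 0, 5)
  ww0 <- watson_williams(list(g, g))
  expect_lt(ww0$F, 1e-10)
  # type-I error near 5% under a common mean
  rej <- vapply(1:200, function(i) {
    watson_williams(list(rvm(50, 1, 5), rvm(50, 1, 5)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
  # power: 90 degrees apart at kappa 5 is detected
  ww <- watson_williams(list(rvm(100, 0, 5), rvm(100, pi / 2, 5)))
  expect_lt(ww$p, 0.01)
  expect_false(ww$validity_warning)
  expect_error_class(watson_williams(list(g)), "validation_error")
})
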