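# Synthetic laminar sessions with known ground truth: four spatially fixed
# depth sources mixed linearly into an 8-channel LFP, a shared wandering theta
# oscillator with controllable theta-phase/gamma-amplitude coupling, behavioral
# state (hold vs pull) band-power modulation, von Mises phase-locked spike
# trains, and a hold-then-pull lever trajectory.

SOURCE_SHAPES <- c("nonreversing_superficial", "deep_reversing",
                   "superficial_reversing", "linear_volume_conducted")

#' Specification of one synthetic LFP source
#'
#' @param loading_shape One of `"nonreversing_superficial"` (Gaussian bump
#'   peaking ~700 um, no polarity reversal), `"deep_reversing"` (deep maximum
#'   ~1450 um, polarity reversal ~1000 um), `"superficial_reversing"`
#'   (superficial maximum, same reversal depth), `"linear_volume_conducted"`
#'   (exactly affine in depth, the signature of a remote, volume-conducted
#'   generator).
#' @param band_powers Named numeric vector `c(theta=, slow_gamma=, fast_gamma=)`
#'   of band variances (mV^2) during the hold state.
#' @param state_gains Named list per band of `c(hold=, pull=)` multiplicative
#'   power factors applied in the two behavioral states.
#' @param pull_delay_ms Named numeric vector (per band) delaying the onset of
#'   the pull-state gain relative to pull onset, in ms (default 0).
#' @param coupling_depth Fraction `[0, 1]` of the gamma amplitude modulated by
#'   theta phase.
#' @param preferred_phase_deg Theta phase (degrees) of maximal gamma amplitude.
#' @param evoked Movement-evoked slow potential locked to each pull onset:
#'   named vector `c(amp =, peak_ms =, width_ms =, biphasic =)` describing a
#'   wave of amplitude `amp` (mV) centered `peak_ms` after onset with SD
#'   `width_ms`; `biphasic` selects the waveform: 0 a Gaussian, 1 its first
#'   derivative (rise-then-fall, odd), 2 its second derivative (triphasic,
#'   even). The three forms are mutually near-orthogonal, so simultaneous
#'   evoked waves in different sources stay nearly uncorrelated. `amp = 0`
#'   disables it. This is the slow peri-movement deflection visible in
#'   onset-triggered component averages, and the part of the signal that
#'   survives the 10 Hz low-pass feeding the reservoir.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(loading_shape,
                        band_powers = c(theta = 0.02, slow_gamma = 0.3,
                                        fast_gamma = 0.1),
                        state_gains = list(theta = c(hold = 1, pull = 1),
                                           slow_gamma = c(hold = 1, pull = 1),
                                           fast_gamma = c(hold = 1, pull = 1)),
                        pull_delay_ms = c(theta = 0, slow_gamma = 0,
                                          fast_gamma = 0),
                        coupling_depth = 0,
                        preferred_phase_deg = 0,
                        evoked = c(amp = 0, peak_ms = 0, width_ms = 150,
                                   biphasic = 0)) {
  if (!loading_shape %in% SOURCE_SHAPES)
    ll_stop("spec_error", sprintf("unknown loading_shape '%s'", loading_shape))
  if (any(band_powers < 0)) ll_stop("spec_error", "band powers must be >= 0")
  if (coupling_depth < 0 || coupling_depth > 1)
    ll_stop("spec_error", "coupling_depth must be in [0, 1]")
  for (b in names(state_gains))
    if (any(state_gains[[b]] < 0))
      ll_stop("spec_error", "state gains must be >= 0")
  structure(list(loading_shape = loading_shape, band_powers = band_powers,
                 state_gains = state_gains, pull_delay_ms = pull_delay_ms,
                 coupling_depth = coupling_depth,
                 preferred_phase_deg = preferred_phase_deg, evoked = evoked),
            class = "source_spec")
}

#' Default four-source configuration
#'
#' The study conditions emulated by the generator: a superficial non-reversing
#' source with hold-dominant slow gamma and the strongest theta-gamma
#' coupling; a deep reversing source whose slow gamma rises ~100 ms after pull
#' onset; a weaker superficial reversing source whose fast gamma peaks ~100 ms
#' after onset; and a theta-carrying, exactly linear volume-conducted source.
#' Fast gamma is pull-enhanced in all local sources. Coupling depths keep the
#' modulation-index ordering (source 1 strongest, source 3 above source 2) and
#' the preferred theta phases keep the volume-conducted source earliest,
#' followed by source 1, then sources 2 and 3. The additive theta oscillation
#' lives only in the volume-conducted source; the local sources feel the
#' shared theta oscillator through their gamma amplitude modulation, which
#' keeps the sources mutually independent enough for blind separation.
#'
#' @return List of four [source_spec()] objects.
#' @export
default_source_specs <- function() {
  list(
    source_spec("nonreversing_superficial",
                band_powers = c(theta = 0, slow_gamma = 0.50, fast_gamma = 0.10),
                state_gains = list(theta = c(hold = 1, pull = 1),
                                   slow_gamma = c(hold = 1, pull = 0.35),
                                   fast_gamma = c(hold = 0.30, pull = 1)),
                coupling_depth = 0.90, preferred_phase_deg = 45,
                evoked = c(amp = 0.35, peak_ms = -150, width_ms = 200, biphasic = 0)),
    source_spec("deep_reversing",
                band_powers = c(theta = 0, slow_gamma = 0.55, fast_gamma = 0.12),
                state_gains = list(theta = c(hold = 1, pull = 1),
                                   slow_gamma = c(hold = 0.65, pull = 1),
                                   fast_gamma = c(hold = 0.30, pull = 1)),
                pull_delay_ms = c(theta = 0, slow_gamma = 100, fast_gamma = 0),
                coupling_depth = 0.75, preferred_phase_deg = 90,
                evoked = c(amp = 0.30, peak_ms = 50, width_ms = 180, biphasic = 1)),
    source_spec("superficial_reversing",
                band_powers = c(theta = 0, slow_gamma = 0.25, fast_gamma = 0.06),
                state_gains = list(theta = c(hold = 1, pull = 1),
                                   slow_gamma = c(hold = 1, pull = 0.45),
                                   fast_gamma = c(hold = 0.35, pull = 1)),
                pull_delay_ms = c(theta = 0, slow_gamma = 0, fast_gamma = 100),
                coupling_depth = 0.85, preferred_phase_deg = 135,
                evoked = c(amp = 0.28, peak_ms = 100, width_ms = 150, biphasic = 0)),
    source_spec("linear_volume_conducted",
                band_powers = c(theta = 0.25, slow_gamma = 0.35, fast_gamma = 0.08),
                state_gains = list(theta = c(hold = 1, pull = 1),
                                   slow_gamma = c(hold = 1, pull = 0.50),
                                   fast_gamma = c(hold = 0.40, pull = 0.70)),
                coupling_depth = 0.60, preferred_phase_deg = 0,
                evoked = c(amp = 0.40, peak_ms = -20, width_ms = 250, biphasic = 2)))
}

#' Default electrode depth grid (um): 8 channels, 150 um spacing
#' @return Numeric vector of depths.
#' @export
default_depths <- function() seq(550, 1600, by = 150)

# closed-form archetype profile at depth x (um); also used by CSD oracles
loading_archetype <- function(shape, x) {
  # two-lobe profiles: the opposite-sign lobe amplitude is chosen analytically
  # so the zero crossing falls exactly at 1000 um; lobe widths were picked to
  # keep the four archetypes mutually distinct under the loading metric
  # (minimum pairwise d ~ 0.23) while preserving the qualitative depth
  # profiles (maxima at ~700, ~1450, superficial; one exactly affine).
  switch(shape,
    nonreversing_superficial = exp(-(x - 700)^2 / (2 * 300^2)),
    deep_reversing = exp(-(x - 1450)^2 / (2 * 200^2)) -
      exp(-(1000 - 1450)^2 / (2 * 200^2) + (1000 - 550)^2 / (2 * 250^2)) *
      exp(-(x - 550)^2 / (2 * 250^2)),
    superficial_reversing = exp(-(x - 550)^2 / (2 * 180^2)) -
      exp(-(1000 - 550)^2 / (2 * 180^2) + (1000 - 1450)^2 / (2 * 300^2)) *
      exp(-(x - 1450)^2 / (2 * 300^2)),
    linear_volume_conducted = 0.1 + 0.9 * (x - min(x)) / (max(x) - min(x)),
    ll_stop("spec_error", sprintf("unknown loading_shape '%s'", shape)))
}

#' Build ground-truth spatial loadings
#'
#' Evaluates each source's archetype profile on the electrode depth grid; every
#' column is normalized so its largest absolute value is 1. The
#' volume-conducted column is exactly affine in depth.
#'
#' @param specs List of [source_spec()] objects.
#' @param depths Electrode depths (um), >= 3 channels.
#' @return Matrix channels x sources with attribute `depths`.
#' @export
make_loadings <- function(specs, depths = default_depths()) {
  if (length(depths) < 3L)
    ll_stop("spec_error", "at least 3 channels are required")
  V <- vapply(specs, function(sp) {
    v <- loading_archetype(sp$loading_shape, depths)
    v / max(abs(v))
  }, numeric(length(depths)))
  attr(V, "depths") <- depths
  V
}

# smooth hold->pull power-gain envelope; raised-cosine ramps of ramp_ms
state_envelope <- function(onsets_s, fs, n, hold, pull,
                           window_ms = c(-200, 300), delay_ms = 0,
                           ramp_ms = 50) {
  env <- rep(hold, n)
  if (hold == pull) return(env)
  t0 <- window_ms[1] + delay_ms
  t1 <- window_ms[2] + delay_ms
  nr <- max(1L, round(ramp_ms / 1000 * fs))
  up <- (1 - cos(seq(0, pi, length.out = nr))) / 2     # 0 -> 1
  for (on in onsets_s) {
    i0 <- round((on + t0 / 1000) * fs) + 1L
    i1 <- round((on + t1 / 1000) * fs) + 1L
    if (i1 < 1L || i0 > n) next
    ramp_in <- i0 + seq_len(nr) - 1L
    ramp_out <- i1 + seq_len(nr) - 1L
    core <- seq.int(min(i0 + nr, n), min(i1, n))
    g <- function(idx, frac) {
      ok <- idx >= 1L & idx <= n
      env[idx[ok]] <<- hold + (pull - hold) * frac[ok]
    }
    g(ramp_in, up)
    if (length(core)) env[core] <- pull
    g(ramp_out, rev(up))
  }
  env
}

#' Generate ground-truth source time courses
#'
#' Each source is a sum over bands of a band-limited Gaussian-noise carrier
#' (unit variance), scaled to the spec's band power, multiplied by the square
#' root of the behavioral state gain envelope and, for the gamma bands, by the
#' theta-phase amplitude-modulation law
#' `1 - kc + kc * (1 + cos(theta - phi0)) / 2`. A single frequency-wandering
#' theta oscillator (4-10 Hz) is shared by all sources; the theta-band content
#' of each source is that oscillator scaled to the spec's theta power.
#'
#' @param specs List of [source_spec()] objects.
#' @param events An [event_table()].
#' @param fs Sampling rate (Hz); must exceed twice the fastest band edge.
#' @param duration Duration (s), covering all event windows.
#' @param seed RNG seed (identical seeds give bit-identical output).
#' @return Matrix sources x time, with attributes `fs`, `theta_phase` (the
#'   shared oscillator's phase series) and `bands`.
#' @export
make_timecourses <- function(specs, events, fs, duration, seed = 1L) {
  if (fs < 2 * 120)
    ll_stop("aliasing_error", "fs must be at least 240 Hz (2 x fastest band edge)")
  if (duration < max(events$pull_onsets) + 0.5)
    ll_stop("validation_error", "duration does not cover all event windows")
  set.seed(seed)
  n <- round(duration * fs)
  bands <- list(theta = c(4, 10), slow_gamma = c(20, 50), fast_gamma = c(60, 120))

  # shared wandering theta oscillator: instantaneous frequency interpolated
  # from slow random control points, clipped to the 4-10 Hz band
  ctrl_t <- seq(0, duration, by = 2)
  ctrl_z <- rnorm(length(ctrl_t), 0, 0.5)
  z <- approx(ctrl_t, ctrl_z, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  f_inst <- 7 + 3 * pmax(-1, pmin(1, z))
  theta_phase <- cumsum(2 * pi * f_inst / fs)

  S <- matrix(0, nrow = length(specs), ncol = n)
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    phi0 <- sp$preferred_phase_deg * pi / 180
    am <- 1 - sp$coupling_depth +
      sp$coupling_depth * (1 + cos(theta_phase - phi0)) / 2
    x <- numeric(n)
    for (b in names(bands)) {
      P <- sp$band_powers[[b]]
      if (P <= 0) next
      g <- sp$state_gains[[b]]
      delay <- if (!is.null(sp$pull_delay_ms)) sp$pull_delay_ms[[b]] else 0
      env <- sqrt(state_envelope(events$pull_onsets, fs, n,
                                 hold = g[["hold"]], pull = g[["pull"]],
                                 delay_ms = delay))
      if (b == "theta") {
        x <- x + sqrt(2 * P) * cos(theta_phase) * env
      } else {
        carrier <- bandpass(rnorm(n), fs, bands[[b]])
        carrier <- carrier / sd(carrier)
        x <- x + sqrt(P) * carrier * env * am
      }
    }
    # movement-evoked slow potential, one wave per pull onset with mild
    # trial-to-trial amplitude/latency jitter
    ev <- sp$evoked
    if (!is.null(ev) && ev[["amp"]] != 0) {
      tt <- (seq_len(n) - 1) / fs
      w_s <- ev[["width_ms"]] / 1000
      for (on in events$pull_onsets) {
        a <- ev[["amp"]] * (1 + 0.1 * rnorm(1))
        pk <- on + (ev[["peak_ms"]] + 20 * rnorm(1)) / 1000
        i0 <- max(1L, round((pk - 4 * w_s) * fs))
        i1 <- min(n, round((pk + 4 * w_s) * fs))
        idx <- i0:i1
        u <- (tt[idx] - pk) / w_s
        wave <- switch(as.character(ev[["biphasic"]]),
          "1" = a * exp(0.5) * u * exp(-u^2 / 2),        # biphasic (odd)
          "2" = a * (1 - u^2) * exp(-u^2 / 2),           # triphasic (even)
          a * exp(-u^2 / 2))                             # monophasic
        x[idx] <- x[idx] + wave
      }
    }
    S[si, ] <- x
  }
  attr(S, "fs") <- fs
  attr(S, "theta_phase") <- theta_phase
  attr(S, "bands") <- bands
  S
}

#' Mix sources into a laminar recording
#'
#' Instantaneous linear mixture `V %*% s` plus channel-independent white
#' Gaussian noise. `noise_sd = 0` gives the exact mixture.
#'
#' @param V Ground-truth loadings, channels x sources (from [make_loadings()]).
#' @param s Source time courses, sources x time (from [make_timecourses()]).
#' @param noise_sd Noise standard deviation (mV); >= 0.
#' @param depths Electrode depths; defaults to `attr(V, "depths")`.
#' @param fs Sampling rate; defaults to `attr(s, "fs")`.
#' @return A [laminar_recording()].
#' @export
mix <- function(V, s, noise_sd = 0, depths = attr(V, "depths"),
                fs = attr(s, "fs")) {
  if (noise_sd < 0) ll_stop("spec_error", "noise_sd must be >= 0")
  if (ncol(V) != nrow(s))
    ll_stop("validation_error", "V and s are not conformable")
  X <- V %*% s
  if (noise_sd > 0)
    X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow = nrow(X))
  laminar_recording(X, depths, fs)
}

# invert A(kappa) = I1(kappa)/I0(kappa) = target mean resultant length
plv_to_kappa <- function(target) {
  if (target <= 0) return(0)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
                   besselI(k, 0, expon.scaled = TRUE) - target
  stats::uniroot(A, c(1e-8, 700), tol = 1e-10)$root
}

#' Generate spikes phase-locked to a reference oscillation
#'
#' Spikes are drawn by Bernoulli thinning of a rate modulated by a von Mises
#' kernel of the band phase of `phase_ref`; the concentration `kappa` is solved
#' numerically so the expected phase-locking value equals `plv_target`.
#' `plv_target = 0` gives a homogeneous Poisson train; `plv_target = 1` places
#' spikes only at the preferred phase.
#'
#' @param phase_ref Reference time course (e.g. a reconstructed component).
#' @param fs Sampling rate of `phase_ref` (Hz).
#' @param band Frequency band whose phase the unit locks to.
#' @param plv_target Target PLV in `[0, 1]`.
#' @param rate Mean firing rate (Hz), > 0.
#' @param preferred_phase Preferred phase (radians, default 0).
#' @param layer `"superficial"` or `"deep"`.
#' @param cell_class `"RS"` or `"FS"`.
#' @param seed RNG seed.
#' @return A [spike_train_set()] with one unit; the unit record carries
#'   `plv_target`, `band` and `preferred_phase` as ground truth.
#' @export
make_spikes <- function(phase_ref, fs, band = c(20, 50), plv_target = 0,
                        rate = 5, preferred_phase = 0, layer = "deep",
                        cell_class = "RS", seed = 1L) {
  if (plv_target < 0 || plv_target > 1)
    ll_stop("spec_error", "plv_target must be in [0, 1]")
  if (rate <= 0) ll_stop("spec_error", "rate must be > 0")
  set.seed(seed)
  filt <- bandpass(phase_ref, fs, band)
  ph <- analytic_phase_amp(filt)$phase
  n <- length(ph)
  if (plv_target >= 1) {
    # degenerate limit: spike exactly at upward crossings of the preferred
    # phase, located by linear interpolation between samples
    d <- wrap_pi(ph - preferred_phase)
    i <- which(d[-n] < 0 & d[-1] >= 0 & abs(d[-n]) < pi / 2)
    frac <- -d[i] / (d[i + 1L] - d[i])
    keep_p <- min(1, rate * n / fs / max(length(i), 1L))
    times <- sort((i - 1L + frac)[runif(length(i)) < keep_p] / fs)
  } else {
    kappa <- plv_to_kappa(plv_target)
    lam <- rate * exp(kappa * cos(ph - preferred_phase)) /
      besselI(kappa, 0)                     # mean ~ rate for uniform phase
    p <- pmin(lam / fs, 1)
    idx <- which(runif(n) < p)
    # uniform jitter centered on the sample keeps spike phases unbiased
    times <- sort(pmin(pmax((idx - 1L + runif(length(idx)) - 0.5) / fs, 0),
                       (n - 1L) / fs))
  }
  spike_train_set(list(list(
    times = times, layer = layer, cell_class = cell_class, id = "u01",
    plv_target = plv_target, band = band, preferred_phase = preferred_phase)))
}

#' Generate a hold-then-pull lever trajectory
#'
#' Flat hold level before each pull, a smooth (raised-cosine) pull excursion
#' starting at the onset, a short plateau, and a smooth return to hold.
#' Trial-to-trial amplitude/duration jitter is parameterized; `jitter = 0`
#' makes all trials identical.
#'
#' @param events An [event_table()] (each onset must be preceded by >= 1 s of
#'   hold; overlapping excursions are rejected).
#' @param fs_lever Sampling rate of the trace (Hz).
#' @param duration Total duration (s); default covers the last onset + 1 s.
#' @param amp Pull amplitude (normalized displacement units).
#' @param rise_ms,plateau_ms,fall_ms Excursion segment durations (ms).
#' @param jitter Relative jitter SD applied to amplitude and durations.
#' @param seed RNG seed.
#' @return Numeric lever trace with attribute `fs`.
#' @export
make_lever <- function(events, fs_lever, duration = NULL, amp = 1,
                       rise_ms = 200, plateau_ms = 150, fall_ms = 300,
                       jitter = 0.05, seed = 1L) {
  onsets <- events$pull_onsets
  if (is.null(duration)) duration <- max(onsets) + 1
  exc_s <- (rise_ms + plateau_ms + fall_ms) / 1000
  if (any(onsets < 1) || any(diff(onsets) < 1 + exc_s * (1 + 3 * jitter)))
    ll_stop("spec_error",
            "each pull needs >= 1 s of hold before it and no overlap with the previous excursion")
  set.seed(seed)
  n <- round(duration * fs_lever)
  lever <- numeric(n)
  jit <- function(x) x * (1 + jitter * rnorm(1))
  for (on in onsets) {
    a <- jit(amp)
    nr <- max(2L, round(jit(rise_ms) / 1000 * fs_lever))
    np <- max(1L, round(jit(plateau_ms) / 1000 * fs_lever))
    nf <- max(2L, round(jit(fall_ms) / 1000 * fs_lever))
    shape <- c(a * (1 - cos(seq(0, pi, length.out = nr))) / 2,
               rep(a, np),
               a * (1 + cos(seq(0, pi, length.out = nf))) / 2)
    i0 <- round(on * fs_lever) + 1L
    idx <- i0 + seq_along(shape) - 1L
    ok <- idx <= n
    lever[idx[ok]] <- shape[ok]
  }
  attr(lever, "fs") <- fs_lever
  lever
}

#' Generate a complete synthetic session
#'
#' Events, lever trajectory, ground-truth loadings and time courses, the mixed
#' noisy recording, and phase-locked spike trains, bundled with the ground
#' truth needed for parameter-recovery tests.
#'
#' @param n_trials Number of lever pulls (default 18).
#' @param fs Sampling rate (Hz, default 1000).
#' @param depths Electrode depths (um).
#' @param specs List of [source_spec()]s (default [default_source_specs()]).
#' @param snr Signal-to-noise power ratio of the mixture (default 10); sets the
#'   white-noise SD from the clean-mixture variance. Ignored when `noise_sd`
#'   is given.
#' @param noise_sd Optional explicit noise SD (mV).
#' @param spike_units Data frame describing units to simulate (columns
#'   `source`, `band_lo`, `band_hi`, `plv`, `rate`, `phase_deg`, `layer`,
#'   `cell_class`); `NULL` for a small default population.
#' @param seed RNG seed; the whole session is deterministic given the seed.
#' @return List with `recording`, `events`, `spikes`, and `truth` (loadings
#'   `V`, time courses `s`, specs, per-unit locking targets, theta phase,
#'   noise_sd).
#' @export
synth_session <- function(n_trials = 18L, fs = 1000, depths = default_depths(),
                          specs = default_source_specs(), snr = 10,
                          noise_sd = NULL, spike_units = NULL, seed = 1L) {
  set.seed(seed)
  gaps <- runif(n_trials, 3.5, 4.5)
  onsets <- 2 + cumsum(gaps) - gaps[1]
  duration <- max(onsets) + 1.5
  events <- event_table(onsets, rewarded = runif(n_trials) < 0.8,
                        duration_s = duration)
  lever <- make_lever(events, fs_lever = fs, duration = duration,
                      seed = seed + 1L)
  events$lever <- as.numeric(lever)
  events$fs_lever <- fs
  V <- make_loadings(specs, depths)
  s <- make_timecourses(specs, events, fs, duration, seed = seed + 2L)
  if (is.null(noise_sd)) noise_sd <- sd(V %*% s) / sqrt(snr)
  set.seed(seed + 3L)
  rec <- mix(V, s, noise_sd = noise_sd, depths = depths, fs = fs)
  if (is.null(spike_units))
    spike_units <- data.frame(
      source = c(1, 1, 2, 4),
      band_lo = c(20, 60, 20, 20), band_hi = c(50, 120, 50, 50),
      plv = c(0.5, 0.4, 0.35, 0.25), rate = c(8, 10, 8, 6),
      phase_deg = c(0, 45, 90, 180),
      layer = c("superficial", "superficial", "deep", "deep"),
      cell_class = c("RS", "FS", "RS", "RS"))
  units <- vector("list", nrow(spike_units))
  for (i in seq_len(nrow(spike_units))) {
    u <- spike_units[i, ]
    st <- make_spikes(s[u$source, ], fs, band = c(u$band_lo, u$band_hi),
                      plv_target = u$plv, rate = u$rate,
                      preferred_phase = u$phase_deg * pi / 180,
                      layer = u$layer, cell_class = u$cell_class,
                      seed = seed + 10L + i)
    units[[i]] <- st$units[[1]]
    units[[i]]$id <- sprintf("u%02d", i)
    units[[i]]$source <- u$source
  }
  spikes <- spike_train_set(units, duration_s = duration)
  list(recording = rec, events = events, spikes = spikes,
       truth = list(V = V, s = s, specs = specs, units = spike_units,
                    theta_phase = attr(s, "theta_phase"),
                    noise_sd = noise_sd, fs = fs, duration = duration))
}

#' Write a synthetic session to a directory
#'
#' Emits the standard file set (`recording.bin`/`.json`, `events.tsv`,
#' `lever.tsv`, `spikes.tsv`) plus `ground_truth.json`.
#'
#' @param session Result of [synth_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_recording(session$recording, file.path(dir, "recording.bin"))
  write_events(session$events, dir)
  write_spikes(session$spikes, dir)
  gt <- list(V = session$truth$V, units = session$truth$units,
             noise_sd = session$truth$noise_sd, fs = session$truth$fs,
             duration = session$truth$duration)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
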