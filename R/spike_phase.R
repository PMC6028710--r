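# Spike-field phase locking: per-spike band phases of reconstructed
# components, Rayleigh circular-uniformity test, phase-locking value, and
# behavioral-state-resolved locked proportions.

#' Band phase of a component at spike times
#'
#' Band-pass filters the reference trace, takes the Hilbert phase, and samples
#' it at spike times by linear interpolation of the unwrapped phase (avoiding
#' sample-quantization bias at low sampling rates).
#'
#' @param spike_times Spike times (s), all inside the trace span.
#' @param ic_trace Reference trace (e.g. a reconstructed component, mV).
#' @param fs Sampling rate of the trace (Hz).
#' @param band Frequency band `(low, high)` in Hz.
#' @return Per-spike phases in radians, wrapped to `(-pi, pi]`.
#' @export
spike_phases <- function(spike_times, ic_trace, fs, band) {
  n <- length(ic_trace)
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > (n - 1) / fs))
    ll_stop("boundary_error", "spike outside the trace span")
  ph <- analytic_phase_amp(bandpass(ic_trace, fs, band))$phase
  unwrapped <- ph[1] + c(0, cumsum(wrap_pi(diff(ph))))
  tt <- (seq_len(n) - 1L) / fs
  wrap_pi(approx(tt, unwrapped, xout = spike_times)$y)
}

#' Rayleigh test of circular uniformity
#'
#' `Z = N * rbar^2` with the standard finite-sample approximation for the
#' p-value; small p rejects uniformity (phase locking).
#'
#' @param phases Phases in radians, `N >= 2`.
#' @return List with `rbar` (mean resultant length), `Z`, `p`, `n`.
#' @export
rayleigh <- function(phases) {
  n <- length(phases)
  if (n < 2L) ll_stop("sample_error", "Rayleigh test needs >= 2 phases")
  rbar <- circ_resultant(phases)$rbar
  R <- n * rbar
  Z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(rbar = rbar, Z = Z, p = min(p, 1), n = n)
}

#' Phase-locking value
#'
#' Magnitude of the mean unit phasor, `PLV = |sum exp(i theta_k)| / N`;
#' 1 for perfect locking, ~`1/sqrt(N)` under uniformity.
#'
#' @param phases Phases in radians, `N >= 1`.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phases) {
  if (!length(phases)) ll_stop("sample_error", "PLV needs >= 1 phase")
  circ_resultant(phases)$rbar
}

#' Phase locking of every unit to one component band
#'
#' @param spikes A [spike_train_set()].
#' @param ic_trace Reference trace (reconstructed component, mV).
#' @param fs Sampling rate (Hz).
#' @param band Frequency band `(low, high)` in Hz.
#' @param ic_index Component index recorded in the output.
#' @param alpha Rayleigh significance level (default 0.05).
#' @param min_spikes Minimum spike count for inclusion (default 50).
#' @return Data frame, one row per included unit: `unit`, `layer`,
#'   `cell_class`, `ic`, `n`, `plv`, `preferred_phase_deg`, `p`, `locked`.
#' @export
spike_field_locking <- function(spikes, ic_trace, fs, band, ic_index = NA_integer_,
                                alpha = 0.05, min_spikes = 50L) {
  rows <- lapply(spikes$units, function(u) {
    if (length(u$times) < max(2L, min_spikes)) return(NULL)
    ph <- spike_phases(u$times, ic_trace, fs, band)
    rt <- rayleigh(ph)
    data.frame(unit = u$id, layer = u$layer, cell_class = u$cell_class,
               ic = ic_index, n = rt$n, plv = plv(ph),
               preferred_phase_deg = (circ_resultant(ph)$mean_dir %% (2 * pi)) * 180 / pi,
               p = rt$p, locked = rt$p < alpha)
  })
  do.call(rbind, rows)
}

# spikes falling in a peri-onset window (ms) of any event
spikes_in_state <- function(times, onsets, window_ms) {
  keep <- rep(FALSE, length(times))
  for (on in onsets)
    keep <- keep | (times >= on + window_ms[1] / 1000 &
                    times <= on + window_ms[2] / 1000)
  times[keep]
}

#' Behavioral-state-resolved locked proportions
#'
#' Restricts each unit's spikes to the hold window (1000-500 ms before pull
#' onset) or the pull window (200 ms before to 300 ms after onset), recomputes
#' the Rayleigh test and PLV per component band, and tabulates the proportion
#' of locked units by layer, cell class, component, band and state. Units with
#' fewer than `min_spikes` in-window spikes are excluded (noted in the
#' `n_excluded` attribute).
#'
#' @param spikes A [spike_train_set()].
#' @param ic_traces Named list of reconstructed component traces.
#' @param fs Sampling rate (Hz).
#' @param events An [event_table()].
#' @param bands Named list of bands (default slow/fast gamma).
#' @param hold_window,pull_window State windows in ms relative to pull onset.
#' @param alpha Rayleigh level (default 0.05).
#' @param min_spikes Minimum in-window spikes per unit/state (default 50).
#' @return Data frame with one row per (layer, cell_class, ic, band, state):
#'   `n_units`, `n_locked`, `proportion`, plus mean PLV of included units.
#' @export
locked_proportions <- function(spikes, ic_traces, fs, events,
                               bands = list(slow_gamma = c(20, 50),
                                            fast_gamma = c(60, 120)),
                               hold_window = c(-1000, -500),
                               pull_window = c(-200, 300),
                               alpha = 0.05, min_spikes = 50L) {
  states <- list(hold = hold_window, pull = pull_window)
  out <- list(); excluded <- 0L
  for (ic in names(ic_traces)) for (bn in names(bands)) {
    # one filtering per (ic, band); phases then sampled per unit/state
    ph_series <- analytic_phase_amp(bandpass(ic_traces[[ic]], fs, bands[[bn]]))$phase
    unwrapped <- ph_series[1] + c(0, cumsum(wrap_pi(diff(ph_series))))
    tt <- (seq_along(ph_series) - 1L) / fs
    for (st in names(states)) {
      recs <- lapply(spikes$units, function(u) {
        ts <- spikes_in_state(u$times, events$pull_onsets, states[[st]])
        if (length(ts) < max(2L, min_spikes)) { excluded <<- excluded + 1L; return(NULL) }
        ph <- wrap_pi(approx(tt, unwrapped, xout = ts)$y)
        data.frame(layer = u$layer, cell_class = u$cell_class,
                   plv = plv(ph), locked = rayleigh(ph)$p < alpha)
      })
      recs <- do.call(rbind, recs)
      if (is.null(recs)) next
      agg <- do.call(rbind, lapply(split(recs, list(recs$layer, recs$cell_class),
                                         drop = TRUE), function(d)
        data.frame(layer = d$layer[1], cell_class = d$cell_class[1],
                   ic = ic, band = bn, state = st, n_units = nrow(d),
                   n_locked = sum(d$locked),
                   proportion = mean(d$locked), mean_plv = mean(d$plv))))
      out[[length(out) + 1L]] <- agg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- excluded
  res
}
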