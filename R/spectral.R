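# Morlet-wavelet spectrograms, Welch power spectral densities, pull-onset
# triggered spectrogram averages, and band-power time courses.

#' Morlet wavelet spectrogram
#'
#' Complex Morlet continuous wavelet transform implemented in the frequency
#' domain: the FFT spectrum is windowed by a Gaussian of width
#' `sigma_f = f / n_cycles` centered on each analysis frequency (the Fourier
#' dual of a Gaussian-envelope complex sinusoid with `n_cycles` cycles), and
#' squared moduli are returned. Scaled so a unit-amplitude sinusoid at an
#' analysis frequency yields power 1 on its ridge. Edges are reflect-padded;
#' a cone-of-influence mask flags samples closer to an edge than the wavelet
#' e-folding time `sqrt(2) n_cycles / (2 pi f)`.
#'
#' @param trace Numeric signal (mV).
#' @param fs Sampling rate (Hz).
#' @param freqs Analysis frequencies (Hz), all below `fs/2` (default 2-150 Hz
#'   in 1 Hz steps, clipped to the Nyquist limit).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param time_ms Optional time axis (ms) to attach.
#' @return Object of class `spectrogram`: `power` (freq x time, amplitude^2
#'   units), `freqs`, `time_ms`, `coi` (logical matrix, TRUE = inside the
#'   cone of influence, i.e. valid), `fs`.
#' @export
morlet_spectrogram <- function(trace, fs, freqs = NULL, n_cycles = 7,
                               time_ms = NULL) {
  if (is.null(freqs)) freqs <- seq(2, min(150, floor(fs / 2) - 1), by = 1)
  if (max(freqs) >= fs / 2)
    ll_stop("spec_error", "analysis frequencies must be below fs/2")
  n <- length(trace)
  pad <- min(n - 1L, ceiling(fs * sqrt(2) * n_cycles / (2 * pi * min(freqs))))
  xp <- c(rev(trace[2:(pad + 1L)]), trace, rev(trace[(n - pad):(n - 1L)]))
  np <- length(xp)
  X <- fft(xp)
  fgrid <- (seq_len(np) - 1L) / np * fs
  pw <- matrix(0, nrow = length(freqs), ncol = n)
  sel <- pad + seq_len(n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_f <- f / n_cycles
    G <- 2 * exp(-(fgrid - f)^2 / (2 * sigma_f^2))   # analytic: +f side only
    coefs <- fft(X * G, inverse = TRUE) / np
    pw[fi, ] <- Mod(coefs[sel])^2
  }
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1L) / fs * 1000
  t_edge <- (seq_len(n) - 1L) / fs
  coi <- matrix(TRUE, nrow = length(freqs), ncol = n)
  for (fi in seq_along(freqs)) {
    efold <- sqrt(2) * n_cycles / (2 * pi * freqs[fi])
    coi[fi, ] <- t_edge >= efold & (rev(t_edge) >= efold)
  }
  structure(list(power = pw, freqs = freqs, time_ms = time_ms, coi = coi,
                 fs = fs, n_cycles = n_cycles),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%g-%g Hz) x %d time points\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$power)))
  invisible(x)
}

#' Welch power spectral density
#'
#' Hamming-windowed, 50%-overlapping segments of `nfft` points, one-sided
#' density normalization (so the PSD integrates to the trace variance).
#'
#' @param trace Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nfft FFT/segment length (default 4096).
#' @return Object of class `psd`: `freq`, `psd` (units^2/Hz), `df`, `nfft`,
#'   `n_segments`.
#' @export
welch_psd <- function(trace, fs, nfft = 4096L) {
  n <- length(trace)
  if (n < nfft)
    ll_stop("length_error", sprintf("trace length %d < nfft %d", n, nfft))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))
  step <- nfft %/% 2L
  starts <- seq(1L, n - nfft + 1L, by = step)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s0 in starts) {
    seg <- trace[s0:(s0 + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (fs * sum(w^2))
    half <- P[seq_len(nfft %/% 2L + 1L)]
    half[2:(nfft %/% 2L)] <- 2 * half[2:(nfft %/% 2L)]
    acc <- acc + half
  }
  structure(list(freq = (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft,
                 psd = acc / length(starts), df = fs / nfft, nfft = nfft,
                 n_segments = length(starts)),
            class = "psd")
}

#' Pull-onset-triggered average spectrogram
#'
#' Either averages a list of per-trial [morlet_spectrogram()]s pointwise, or
#' computes the full-recording spectrogram of `x` once, cuts the peri-onset
#' windows (only those fully inside the recording) and averages them, aligned
#' so time 0 is the pull onset.
#'
#' @param x List of `spectrogram` objects with identical grids, or a numeric
#'   trace.
#' @param fs,events,window,freqs,n_cycles Used when `x` is a trace: sampling
#'   rate, an [event_table()], the `(pre_s, post_s)` window (default 1 s
#'   before to 0.5 s after onset), analysis frequencies and wavelet cycles.
#' @return A `spectrogram` whose `time_ms` axis is peri-onset, with an extra
#'   field `n_trials`.
#' @export
triggered_power <- function(x, fs = NULL, events = NULL,
                            window = c(1.0, 0.5), freqs = NULL, n_cycles = 7) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "spectrogram"))) {
    if (length(x) < 1L) ll_stop("spec_error", "need >= 1 trial")
    pw <- Reduce(`+`, lapply(x, `[[`, "power")) / length(x)
    out <- x[[1]]
    out$power <- pw
    out$n_trials <- length(x)
    return(out)
  }
  sp <- morlet_spectrogram(x, fs, freqs = freqs, n_cycles = n_cycles)
  n_pre <- round(window[1] * fs); n_post <- round(window[2] * fs)
  onset_idx <- round(events$pull_onsets * fs) + 1L
  keep <- onset_idx - n_pre >= 1L & onset_idx + n_post <= length(x)
  onset_idx <- onset_idx[keep]
  if (!length(onset_idx)) ll_stop("spec_error", "no trial window fits the recording")
  acc <- 0
  for (oi in onset_idx)
    acc <- acc + sp$power[, (oi - n_pre):(oi + n_post), drop = FALSE]
  out <- sp
  out$power <- acc / length(onset_idx)
  out$time_ms <- (seq_len(n_pre + n_post + 1L) - 1L - n_pre) / fs * 1000
  out$coi <- matrix(TRUE, nrow = nrow(out$power), ncol = ncol(out$power))
  out$n_trials <- length(onset_idx)
  out
}

#' Band-power time course of a spectrogram
#'
#' For a frequency band, the power trace at the in-band frequency of maximum
#' power (e.g. slow gamma, 20-50 Hz); alternatively, with `probe_hz` set, the
#' trace at the grid frequency nearest the probe (fast gamma is probed at
#' 80 Hz). Peak power and peak frequency are reported.
#'
#' @param spect A `spectrogram`.
#' @param band Numeric pair `(low, high)` in Hz, inside the frequency grid.
#' @param probe_hz Optional single probe frequency (Hz).
#' @return Object of class `band_power_trace`: `band`, `power` (vs time),
#'   `time_ms`, `peak_power`, `peak_freq`.
#' @export
band_power <- function(spect, band, probe_hz = NULL) {
  in_band <- spect$freqs >= band[1] & spect$freqs <= band[2]
  if (!any(in_band))
    ll_stop("spec_error", "band lies outside the spectrogram frequency grid")
  if (!is.null(probe_hz)) {
    fi <- which.min(abs(spect$freqs - probe_hz))
  } else {
    rows <- which(in_band)
    sub <- spect$power[rows, , drop = FALSE]
    fi <- rows[which(sub == max(sub), arr.ind = TRUE)[1, 1]]
  }
  tr <- spect$power[fi, ]
  structure(list(band = band, power = tr, time_ms = spect$time_ms,
                 peak_power = max(tr), peak_freq = spect$freqs[fi]),
            class = "band_power_trace")
}
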