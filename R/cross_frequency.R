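# Theta-gamma phase-amplitude coupling: FIR filtering, analytic phase and
# envelope, 18-bin phase-amplitude distributions, the Tort modulation index,
# trial-shuffling surrogate significance, and Watson-Williams comparison of
# preferred phases.

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass designed with [signal::fir1()] and applied
#' as a single-pass linear-phase filter with exact group-delay compensation, so
#' the output is zero-phase. Edges are reflect-padded before filtering.
#'
#' @param trace Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param band Numeric pair `(low, high)` in Hz, inside `(0, fs/2)`.
#' @param order Filter order (even); default 4.5 cycles of the low band edge,
#'   sharp enough that a tone 2 Hz inside the theta passband keeps its
#'   amplitude within 5%.
#' @return Filtered trace, same length as the input.
#' @export
bandpass <- function(trace, fs, band, order = NULL) {
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    ll_stop("spec_error", "band must satisfy 0 < low < high < fs/2")
  n <- length(trace)
  if (is.null(order)) order <- round(4.5 * fs / band[1])
  order <- 2L * ceiling(order / 2)          # even -> odd tap count, exact delay
  max_order <- 2L * floor((n - 1L) / 2)
  if (order > max_order) order <- max_order
  if (order < 6L)
    ll_stop("spec_error", "trace too short for the requested band-pass filter")
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  half <- order / 2
  # reflect-pad so the centered convolution is defined everywhere
  xp <- c(rev(trace[2:(half + 1L)]), trace, rev(trace[(n - half):(n - 1L)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Low-pass filter a trace (zero-phase)
#'
#' Forward-backward 4th-order Butterworth low-pass; used to condition reservoir
#' inputs (rate models are insensitive to fast input fluctuations).
#'
#' @param trace Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz).
#' @return Filtered trace.
#' @export
lowpass <- function(trace, fs, cutoff = 10) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    ll_stop("spec_error", "cutoff must be inside (0, fs/2)")
  bt <- signal::butter(4, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bt, trace))
}

#' Analytic signal via the Hilbert transform
#' @param x Real numeric vector.
#' @return Complex vector whose modulus is the envelope and argument the phase.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope
#'
#' Hilbert-transform phase (radians in `(-pi, pi]`, cosine convention: 0 at the
#' filtered-oscillation peak) and non-negative amplitude envelope of a
#' band-limited, zero-mean trace.
#'
#' @param filtered Band-pass-filtered numeric trace.
#' @return List with `phase`, `amplitude`, and `degenerate` (TRUE when the
#'   trace is identically zero, in which case the phase is undefined/NA).
#' @export
analytic_phase_amp <- function(filtered) {
  if (all(filtered == 0)) {
    return(list(phase = rep(NA_real_, length(filtered)),
                amplitude = numeric(length(filtered)), degenerate = TRUE))
  }
  z <- analytic_signal(filtered)
  list(phase = Arg(z), amplitude = Mod(z), degenerate = FALSE)
}

#' Pick the theta reference channel of a recording
#'
#' The theta phase reference is always extracted from the raw LFP, using the
#' electrode with the highest mean power in the theta band.
#'
#' @param rec A [laminar_recording()].
#' @param band Theta band in Hz (default 4-10).
#' @return List with `channel` (index) and `trace` (that channel's raw LFP).
#' @export
theta_reference <- function(rec, band = c(4, 10)) {
  pw <- apply(rec$samples, 1L, function(x) mean(bandpass(x, rec$fs, band)^2))
  k <- which.max(pw)
  list(channel = k, trace = rec$samples[k, ], power = pw)
}

#' Phase-binned amplitude distribution
#'
#' Means of the amplitude envelope over `n_bins` equal phase bins covering
#' 0-360 degrees, normalized to sum to 1 (a distribution-like function).
#'
#' @param theta_phase Phase series in radians.
#' @param gamma_env Amplitude envelope series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return Numeric vector of `n_bins` normalized bin values, with attribute
#'   `bin_centers_deg`.
#' @export
phase_amp_distribution <- function(theta_phase, gamma_env, n_bins = 18L) {
  if (length(theta_phase) != length(gamma_env))
    ll_stop("validation_error", "phase and envelope series must have equal length")
  keep <- is.finite(theta_phase) & is.finite(gamma_env)
  theta_phase <- theta_phase[keep]; gamma_env <- gamma_env[keep]
  if (!length(theta_phase))
    ll_stop("degenerate_error", "no finite phase/envelope samples")
  ph <- theta_phase %% (2 * pi)                 # [0, 2pi)
  idx <- pmin(floor(ph / (2 * pi / n_bins)) + 1L, n_bins)
  sums <- numeric(n_bins); cnts <- numeric(n_bins)
  ts <- tapply(gamma_env, idx, sum)
  tc <- tapply(gamma_env, idx, length)
  sums[as.integer(names(ts))] <- ts
  cnts[as.integer(names(tc))] <- tc
  if (any(cnts == 0))
    warning("empty phase bin(s) set to 0 before normalization",
            call. = FALSE)
  m <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  if (sum(m) <= 0)
    ll_stop("degenerate_error", "zero amplitude in every phase bin")
  p <- m / sum(m)
  attr(p, "bin_centers_deg") <- (seq_len(n_bins) - 0.5) * 360 / n_bins
  p
}

#' Tort modulation index
#'
#' Normalized Kullback-Leibler divergence of the phase-amplitude distribution
#' from uniform: `MI = (log N - H) / log N` with Shannon entropy `H` in nats.
#' 0 means no coupling; 1 means all amplitude concentrated in one phase bin.
#'
#' @param bins Normalized phase-amplitude distribution (sums to 1).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(bins) {
  if (any(bins < 0)) ll_stop("spec_error", "bins must be non-negative")
  if (abs(sum(bins) - 1) > 1e-6)
    ll_stop("spec_error", "bins must sum to 1")
  n <- length(bins)
  p <- bins[bins > 0]
  H <- -sum(p * log(p))
  (log(n) - H) / log(n)
}

#' Phase-amplitude coupling of one phase/envelope pair
#'
#' Convenience wrapper: bins the envelope by phase, computes the modulation
#' index and the preferred phase (bin of maximum amplitude).
#'
#' @inheritParams phase_amp_distribution
#' @return List with `bins`, `mi`, `preferred_phase_deg`.
#' @export
coupling_mi <- function(theta_phase, gamma_env, n_bins = 18L) {
  b <- phase_amp_distribution(theta_phase, gamma_env, n_bins)
  list(bins = b, mi = modulation_index(b),
       preferred_phase_deg = attr(b, "bin_centers_deg")[which.max(b)])
}

#' Surrogate significance of the modulation index
#'
#' Observed MI from the matched phase/envelope trial pairs; the null pairs the
#' phase series of one randomly chosen trial with the envelope of a different
#' randomly chosen trial (`n_surr` such pairings). Assuming the surrogate MIs
#' are normal, the p-value is the upper tail of the fitted normal; an empirical
#' quantile p-value is reported alongside for robustness.
#'
#' @param phase_trials List of per-trial phase series (radians).
#' @param env_trials List of per-trial envelope series, matching lengths.
#' @param n_surr Number of surrogates (default 200).
#' @param alpha Significance level (default 0.01).
#' @param n_bins Number of phase bins (default 18).
#' @param seed Optional RNG seed for the surrogate pairing.
#' @return Object of class `coupling_result`: bins, `mi`, `null_mean`,
#'   `null_sd`, `p` (normal fit), `p_empirical`, `significant`,
#'   `preferred_phase_deg`.
#' @export
surrogate_mi <- function(phase_trials, env_trials, n_surr = 200L,
                         alpha = 0.01, n_bins = 18L, seed = NULL) {
  n_tr <- length(phase_trials)
  if (n_tr < 2L || length(env_trials) != n_tr)
    ll_stop("insufficient_trials_error",
            "at least 2 matched phase/envelope trials are required")
  if (!is.null(seed)) set.seed(seed)
  obs <- coupling_mi(unlist(phase_trials), unlist(env_trials), n_bins)
  # precompute per-trial bin indices and envelopes for fast surrogate MIs
  width <- 2 * pi / n_bins
  bin_idx <- lapply(phase_trials, function(ph) {
    ph <- ph %% (2 * pi)
    pmin(floor(ph / width) + 1L, n_bins)
  })
  null_mi <- numeric(n_surr)
  for (s in seq_len(n_surr)) {
    i <- sample.int(n_tr, 1L)
    j <- sample.int(n_tr - 1L, 1L)
    if (j >= i) j <- j + 1L                    # envelope from a different trial
    idx <- bin_idx[[i]]; env <- env_trials[[j]]
    L <- min(length(idx), length(env))
    sums <- numeric(n_bins); cnts <- numeric(n_bins)
    ts <- tapply(env[seq_len(L)], idx[seq_len(L)], sum)
    tc <- tapply(env[seq_len(L)], idx[seq_len(L)], length)
    sums[as.integer(names(ts))] <- ts
    cnts[as.integer(names(tc))] <- tc
    m <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
    null_mi[s] <- modulation_index(m / sum(m))
  }
  mu <- mean(null_mi); sdv <- sd(null_mi)
  p_norm <- pnorm(obs$mi, mean = mu, sd = sdv, lower.tail = FALSE)
  p_emp <- (1 + sum(null_mi >= obs$mi)) / (n_surr + 1)
  structure(
    list(bins = obs$bins, mi = obs$mi,
         preferred_phase_deg = obs$preferred_phase_deg,
         null_mean = mu, null_sd = sdv, p = p_norm, p_empirical = p_emp,
         significant = p_norm < alpha, alpha = alpha, n_surr = n_surr),
    class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling_result> MI = %.4f (null %.4f +/- %.4f), p = %.3g%s, preferred phase %g deg\n",
    x$mi, x$null_mean, x$null_sd, x$p,
    if (x$significant) " *" else "", x$preferred_phase_deg))
  invisible(x)
}

# Circular statistics ---------------------------------------------------------

#' Mean resultant length and mean direction of circular samples
#' @noRd
circ_resultant <- function(phases) {
  z <- mean(exp(1i * phases))
  list(rbar = Mod(z), mean_dir = Arg(z))
}

# Best-fitting von Mises concentration for a mean resultant length
# (Fisher 1993 approximation to the inverse of A(kappa) = I1/I0).
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal circular means
#'
#' One-way circular analogue of ANOVA with the usual concentration-based
#' correction factor. Valid when the samples are reasonably concentrated; a
#' `validity_warning` field is set when the pooled mean resultant length is
#' below 0.45.
#'
#' @param groups List of numeric vectors of phases (radians), >= 2 groups with
#'   >= 2 samples each.
#' @return List with `F`, `p`, `df1`, `df2`, `kappa`, `validity_warning`.
#' @export
watson_williams <- function(groups) {
  k <- length(groups)
  if (k < 2L || any(vapply(groups, length, integer(1)) < 2L))
    ll_stop("validation_error", "need >= 2 groups with >= 2 samples each")
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  Ri <- vapply(groups, function(g) length(g) * circ_resultant(g)$rbar, numeric(1))
  R <- N * circ_resultant(unlist(groups))$rbar
  rw <- sum(Ri) / N
  kap <- a1inv(rw)
  K <- 1 + 3 / (8 * kap)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(Fstat, 0)
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = k - 1, df2 = N - k, kappa = kap,
       validity_warning = rw < 0.45)
}
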