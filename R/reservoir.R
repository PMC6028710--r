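# The rate-based recurrent reservoir driven by component inputs, with a
# FORCE-trained linear readout reproducing the lever trajectory.

#' Reservoir parameters
#'
#' @param N_G Number of reservoir neurons (default 300).
#' @param tau Membrane time constant in ms (default 50).
#' @param g_G Recurrent gain (default 1.5; chosen so the pre-training network
#'   is chaotic).
#' @param p Recurrent connection probability (default 0.1).
#' @param N_I Number of input channels (default 4 components).
#' @param dt Euler integration step in ms (default 1; must be <= tau/10).
#' @return Object of class `reservoir_params`.
#' @export
reservoir_params <- function(N_G = 300L, tau = 50, g_G = 1.5, p = 0.1,
                             N_I = 4L, dt = 1) {
  if (dt > tau / 10)
    ll_stop("spec_error", "dt must be <= tau/10 for a stable Euler step")
  if (p < 0 || p > 1) ll_stop("spec_error", "p must be in [0, 1]")
  structure(list(N_G = as.integer(N_G), tau = tau, g_G = g_G, p = p,
                 N_I = as.integer(N_I), dt = dt),
            class = "reservoir_params")
}

#' Input wiring configuration
#'
#' @param assignment `"one_random_ic_per_neuron"` (each neuron receives one
#'   randomly assigned component), `"partitioned_equal_no_overlap"` (the
#'   components project to near-equal, disjoint neuron groups), or
#'   `"single_ic"` (all neurons receive component `single_ic`).
#' @param single_ic Component index used when `assignment = "single_ic"`.
#' @param cutoff Input low-pass cutoff in Hz (default 10; rate dynamics are
#'   insensitive to faster input fluctuations).
#' @param range Input normalization range (default `c(-1, 1)`).
#' @return Object of class `input_config`.
#' @export
input_config <- function(assignment = c("one_random_ic_per_neuron",
                                        "partitioned_equal_no_overlap",
                                        "single_ic"),
                         single_ic = 1L, cutoff = 10, range = c(-1, 1)) {
  assignment <- match.arg(assignment)
  structure(list(assignment = assignment, single_ic = as.integer(single_ic),
                 cutoff = cutoff, range = range),
            class = "input_config")
}

#' Build a reservoir model
#'
#' Recurrent weights are a Bernoulli(`p`) connectivity mask with Gaussian
#' entries scaled to variance `2/(p N_G)`: the standard `1/(p N_G)`
#' normalization of FORCE-trained chaotic networks, doubled because the
#' rectified rate nonlinearity silences half of the units and would otherwise
#' halve the network's mean-square gain. With this scaling the stated `g_G`
#' keeps its conventional meaning and the pre-training network is chaotic at
#' `g_G = 1.5`.
#' Feedback weights from the readout are uniform on `(-1, 1)`; each neuron's
#' input weight on its assigned channel is uniform on `(-1, 1)` and zero
#' elsewhere; the readout starts at zero.
#'
#' @param params A [reservoir_params()].
#' @param cfg An [input_config()].
#' @param seed RNG seed; seeded builds are identical run to run.
#' @return Object of class `reservoir_model` with weights `JGG`, `JGz`, `JGI`,
#'   readout `w`, RLS matrix `P`, state `x`, and the parameters.
#' @export
reservoir_build <- function(params = reservoir_params(), cfg = input_config(),
                            seed = 1L) {
  set.seed(seed)
  N <- params$N_G; NI <- params$N_I
  JGG <- if (params$p > 0) {
    mask <- matrix(rbinom(N * N, 1L, params$p), N, N)
    mask * matrix(rnorm(N * N, 0, sqrt(2 / (params$p * N))), N, N)
  } else matrix(0, N, N)
  JGz <- runif(N, -1, 1)
  assign_ic <- switch(cfg$assignment,
    one_random_ic_per_neuron = sample.int(NI, N, replace = TRUE),
    partitioned_equal_no_overlap = rep_len(sample.int(NI), N)[order(runif(N))],
    single_ic = rep(cfg$single_ic, N))
  JGI <- matrix(0, N, NI)
  JGI[cbind(seq_len(N), assign_ic)] <- runif(N, -1, 1)
  structure(list(params = params, cfg = cfg, JGG = JGG, JGz = JGz, JGI = JGI,
                 w = numeric(N), P = diag(N), x = rnorm(N, 0, 0.5),
                 assign_ic = assign_ic, seed = seed),
            class = "reservoir_model")
}

#' @export
print.reservoir_model <- function(x, ...) {
  cat(sprintf("<reservoir_model> N_G = %d, tau = %g ms, g_G = %g, p = %g, %d input channels (%s)\n",
              x$params$N_G, x$params$tau, x$params$g_G, x$params$p,
              x$params$N_I, x$cfg$assignment))
  invisible(x)
}

#' Condition component traces for the reservoir
#'
#' Low-pass filters each channel (default 10 Hz) and affinely maps it so its
#' minimum and maximum over the supplied (training) data become -1 and +1.
#'
#' @param ic_mat Matrix channels x time of component traces.
#' @param fs Sampling rate (Hz).
#' @param cfg An [input_config()] (cutoff and range).
#' @return Matrix of conditioned inputs, same shape, attribute `fs`.
#' @export
prepare_inputs <- function(ic_mat, fs, cfg = input_config()) {
  if (is.null(dim(ic_mat))) ic_mat <- matrix(ic_mat, nrow = 1L)
  out <- matrix(0, nrow(ic_mat), ncol(ic_mat))
  for (i in seq_len(nrow(ic_mat))) {
    if (diff(range(ic_mat[i, ])) <= 1e-10 * max(abs(ic_mat[i, ]), 1))
      ll_stop("degenerate_error", "constant input trace cannot be normalized")
    y <- lowpass(ic_mat[i, ], fs, cfg$cutoff)
    rng <- range(y)
    if (diff(rng) <= 1e-10 * max(abs(rng), 1))
      ll_stop("degenerate_error", "input trace is constant after filtering")
    out[i, ] <- cfg$range[1] +
      (y - rng[1]) / diff(rng) * (cfg$range[2] - cfg$range[1])
  }
  attr(out, "fs") <- fs
  out
}

# resample an input matrix to the integration grid (dt ms per step)
resample_inputs <- function(inputs, fs, dt, n_steps) {
  tt_in <- (seq_len(ncol(inputs)) - 1L) / fs * 1000
  tt_out <- (seq_len(n_steps) - 1L) * dt
  t(vapply(seq_len(nrow(inputs)), function(i)
    approx(tt_in, inputs[i, ], xout = tt_out, rule = 2)$y,
    numeric(n_steps)))
}

#' Simulate the reservoir
#'
#' Explicit Euler integration of the rate dynamics with readout feedback;
#' learning off.
#'
#' @param model A [reservoir_build()] result.
#' @param inputs Matrix N_I x time of conditioned inputs on the integration
#'   grid (one column per `dt` step), or `NULL` for input-free dynamics.
#' @param duration_ms Simulation length (ms); required when `inputs` is NULL.
#' @param record Return the full rate trajectory (default TRUE).
#' @param carry_state Start from the model's stored state and return the model
#'   with the final state stored (default FALSE: start from the stored state
#'   but do not modify the model).
#' @return List with `z` (readout trace), `rates` (N_G x steps if recorded),
#'   `x` (final state), `model` (state-updated copy when `carry_state`).
#' @export
reservoir_simulate <- function(model, inputs = NULL, duration_ms = NULL,
                               record = TRUE, carry_state = FALSE) {
  p <- model$params
  if (is.null(inputs)) {
    if (is.null(duration_ms)) ll_stop("spec_error", "duration_ms required without inputs")
    n_steps <- round(duration_ms / p$dt)
    inputs <- matrix(0, p$N_I, n_steps)
  }
  res <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                           model$w, model$P, inputs,
                           numeric(ncol(inputs)), p$dt, p$tau, p$g_G,
                           FALSE, 1L, record)
  out <- list(z = as.numeric(res$z), x = as.numeric(res$x))
  if (record) out$rates <- res$rates
  if (carry_state) { model$x <- out$x; out$model <- model }
  out
}

#' Train the readout with FORCE learning
#'
#' Recursive-least-squares updates of the readout weights while the network
#' runs through the training trials (targets fed back through the readout
#' loop). Trial order is shuffled each epoch (seeded); state is carried across
#' trials with a washout period before each trial during which learning is
#' off. Training fails with a classed error if the epoch error grows tenfold.
#'
#' @param model A [reservoir_build()] result.
#' @param inputs_trials List of N_I x steps matrices (integration grid), one
#'   per trial.
#' @param targets_trials List of target readout traces (same length as the
#'   trial's columns), e.g. lever segments from 1 s before to 500 ms after
#'   pull onset.
#' @param n_epochs Training epochs (default 10).
#' @param rls_alpha RLS regularizer; `P` starts at `I/alpha` (default 1).
#' @param update_every RLS update interval in steps (default 2).
#' @param washout_ms Pre-trial washout (default 200 ms).
#' @param seed Seed for the epoch shuffling.
#' @return List with `model` (trained), `error_curve` (per-epoch mean absolute
#'   training error), `nrmse_train` (post-training autonomous rollout error,
#'   normalized by the target SD).
#' @export
force_train <- function(model, inputs_trials, targets_trials, n_epochs = 10L,
                        rls_alpha = 1, update_every = 2L, washout_ms = 200,
                        seed = 1L) {
  p <- model$params
  n_trials <- length(inputs_trials)
  if (n_trials < 1L || length(targets_trials) != n_trials)
    ll_stop("spec_error", "need matching, non-empty input and target trial lists")
  model$P <- diag(p$N_G) / rls_alpha
  set.seed(seed)
  nw <- round(washout_ms / p$dt)
  err_curve <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n_trials)
    tot <- 0; cnt <- 0L
    for (tr in ord) {
      inp <- inputs_trials[[tr]]
      if (nw > 0) {
        wash <- matrix(inp[, 1L], p$N_I, nw)
        r0 <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                                model$w, model$P, wash, numeric(nw),
                                p$dt, p$tau, p$g_G, FALSE, 1L, FALSE)
        model$x <- as.numeric(r0$x)
      }
      res <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                               model$w, model$P, inp, targets_trials[[tr]],
                               p$dt, p$tau, p$g_G, TRUE, as.integer(update_every),
                               FALSE)
      model$x <- as.numeric(res$x); model$w <- as.numeric(res$w)
      model$P <- res$P
      tot <- tot + sum(res$err); cnt <- cnt + length(res$err)
    }
    err_curve[ep] <- tot / cnt
    if (ep > 1L && err_curve[ep] > 10 * err_curve[1L])
      ll_stop("training_failure_error",
              sprintf("FORCE diverged at epoch %d (error %.3g vs initial %.3g)",
                      ep, err_curve[ep], err_curve[1L]))
  }
  # autonomous test rollout: learning off, feedback on
  sse <- 0; n_all <- 0L; tgt_all <- unlist(targets_trials)
  for (tr in seq_len(n_trials)) {
    inp <- inputs_trials[[tr]]
    if (nw > 0) {
      wash <- matrix(inp[, 1L], p$N_I, nw)
      r0 <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                              model$w, model$P, wash, numeric(nw),
                              p$dt, p$tau, p$g_G, FALSE, 1L, FALSE)
      model$x <- as.numeric(r0$x)
    }
    sim <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                             model$w, model$P, inp, numeric(ncol(inp)),
                             p$dt, p$tau, p$g_G, FALSE, 1L, FALSE)
    model$x <- as.numeric(sim$x)
    sse <- sse + sum((as.numeric(sim$z) - targets_trials[[tr]])^2)
    n_all <- n_all + ncol(inp)
  }
  nrmse <- sqrt(sse / n_all) / sd(tgt_all)
  list(model = model, error_curve = err_curve, nrmse_train = nrmse)
}

#' Trial-averaged, min-max-normalized reservoir responses
#'
#' Simulates every trial (learning off, feedback on), averages each neuron's
#' rate over trials, and normalizes each neuron's average between its minimum
#' and maximum. Neurons with a flat average (normalization degenerate) are set
#' to 0 and flagged so the subtype classifier treats them as non-phasic.
#'
#' @param model A trained [reservoir_build()] model.
#' @param inputs_trials List of N_I x steps input matrices.
#' @param washout_ms Pre-trial washout (default 200 ms).
#' @return Matrix neurons x time in `[0, 1]`, attributes `flat` (logical per
#'   neuron) and `time_ms` when the inputs carry one.
#' @export
collect_responses <- function(model, inputs_trials, washout_ms = 200) {
  p <- model$params
  nw <- round(washout_ms / p$dt)
  acc <- 0
  for (tr in seq_along(inputs_trials)) {
    inp <- inputs_trials[[tr]]
    if (nw > 0) {
      wash <- matrix(inp[, 1L], p$N_I, nw)
      r0 <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                              model$w, model$P, wash, numeric(nw),
                              p$dt, p$tau, p$g_G, FALSE, 1L, FALSE)
      model$x <- as.numeric(r0$x)
    }
    sim <- reservoir_run_cpp(model$x, model$JGG, model$JGz, model$JGI,
                             model$w, model$P, inp, numeric(ncol(inp)),
                             p$dt, p$tau, p$g_G, FALSE, 1L, TRUE)
    model$x <- as.numeric(sim$x)
    acc <- acc + sim$rates
  }
  avg <- acc / length(inputs_trials)
  rng <- apply(avg, 1L, range)
  flat <- rng[2, ] - rng[1, ] <= 0
  norm <- (avg - rng[1, ]) / ifelse(rng[2, ] - rng[1, ] > 0,
                                    rng[2, ] - rng[1, ], 1)
  norm[flat, ] <- 0
  attr(norm, "flat") <- flat
  attr(norm, "time_ms") <- attr(inputs_trials[[1]], "time_ms")
  norm
}
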