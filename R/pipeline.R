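# End-to-end orchestration: synthesize a session, decompose it, characterize
# the components, quantify coupling and spike locking, train the reservoir in
# the different input conditions, and classify the learned responses. Every
# stage writes plain-text artifacts and echoes its parameters.

#' Pipeline configuration
#'
#' Validated, schema-checked configuration for [run_pipeline()]. Unknown keys
#' are rejected.
#'
#' @param seed Master RNG seed; every stage derives from it.
#' @param out_dir Output directory for artifacts.
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "decompose", "characterize", "coupling", "spikes",
#'   "reservoir", "subtypes")`.
#' @param n_trials,fs Synthetic-session size (default 18 trials at 1000 Hz).
#' @param var_frac PCA variance fraction (default 0.99).
#' @param n_components Number of major components carried forward (default 4).
#' @param bands Named list of gamma bands for coupling/locking.
#' @param theta_band Theta band (default 4-10 Hz).
#' @param n_surrogates Surrogates for coupling significance (default 200).
#' @param hold_window,pull_window Behavioral windows (ms).
#' @param reservoir Reservoir parameter overrides, passed to
#'   [reservoir_params()].
#' @param n_epochs FORCE training epochs (default 10).
#' @param conditions Input conditions for the reservoir stage: `"all"` and/or
#'   component indices (default `list("all", 1, 2, 3, 4)`).
#' @param min_spikes Minimum spikes per unit/state for locking tables.
#' @param make_figures Write PNG figures (default FALSE).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("laminarLFP_"),
                            stages = c("synth", "decompose", "characterize",
                                       "coupling", "spikes", "reservoir",
                                       "subtypes"),
                            n_trials = 18L, fs = 1000, var_frac = 0.99,
                            n_components = 4L,
                            bands = list(slow_gamma = c(20, 50),
                                         fast_gamma = c(60, 120)),
                            theta_band = c(4, 10), n_surrogates = 200L,
                            hold_window = c(-1000, -500),
                            pull_window = c(-200, 300),
                            reservoir = list(), n_epochs = 10L,
                            conditions = list("all", 1L, 2L, 3L, 4L),
                            min_spikes = 50L, make_figures = FALSE) {
  known <- c("synth", "decompose", "characterize", "coupling", "spikes",
             "reservoir", "subtypes")
  if (!all(stages %in% known))
    ll_stop("config_error", sprintf("unknown stage(s): %s",
                                    paste(setdiff(stages, known), collapse = ", ")))
  if (!all(names(reservoir) %in% names(formals(reservoir_params))))
    ll_stop("config_error", "unknown reservoir parameter override")
  cfg <- as.list(environment())
  cfg$known <- NULL
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(dir, stage, msg) {
  cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
      file = file.path(dir, "pipeline.log"), append = TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order. Artifacts (TSV tables,
#' `summary.json`, optional PNG figures) are written under `config$out_dir`;
#' the summary echoes the seed and parameters, so identical configurations
#' produce identical summaries.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the summary.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    ll_stop("config_error", "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed,
                  params = config[setdiff(names(config), c("out_dir"))])
  res <- list()

  session <- NULL
  if ("synth" %in% config$stages) {
    pipeline_log(config$out_dir, "synth", sprintf("seed %d", config$seed))
    session <- synth_session(n_trials = config$n_trials, fs = config$fs,
                             seed = config$seed)
    write_session(session, file.path(config$out_dir, "session"))
    res$session <- session
    summary$synth <- list(n_trials = config$n_trials, fs = config$fs,
                          noise_sd = session$truth$noise_sd)
  }

  dec <- NULL; profiles <- NULL
  if ("decompose" %in% config$stages) {
    if (is.null(session)) ll_stop("stage_failure", "decompose needs the synth stage")
    pipeline_log(config$out_dir, "decompose", sprintf("var_frac %g", config$var_frac))
    dec <- run_ica(session$recording, var_frac = config$var_frac,
                   seed = config$seed)
    ncomp <- min(config$n_components, ncol(dec$V))
    profiles <- lapply(seq_len(ncomp), function(n) reconstruct_ic(dec, n))
    ld <- data.frame(channel = seq_along(dec$depths), depth_um = dec$depths)
    for (n in seq_len(ncomp)) ld[[sprintf("IC%d", n)]] <- dec$V[, n]
    write_tsv(ld, file.path(config$out_dir, "loadings.tsv"))
    write_tsv(data.frame(ic = seq_along(relative_contribution(dec)),
                         contribution = relative_contribution(dec)),
              file.path(config$out_dir, "contributions.tsv"))
    res$decomposition <- dec; res$profiles <- profiles
    summary$decompose <- list(k = ncol(dec$V), var_retained = dec$var_retained)
  }

  if ("characterize" %in% config$stages && !is.null(dec)) {
    pipeline_log(config$out_dir, "characterize", "loading geometry")
    ncomp <- length(profiles)
    params <- loading_distance_params(h = session$recording$h)
    mt <- match_components(dec$V[, seq_len(ncomp), drop = FALSE],
                           session$truth$V, params)
    rows <- lapply(seq_len(ncomp), function(n) {
      vc <- is_volume_conducted(dec$V[, n], session$recording$h)
      data.frame(ic = n, matched_source = mt$assignment[n],
                 match_distance = mt$distances[n],
                 volume_conducted = vc$volume_conducted,
                 linearity_score = vc$score,
                 max_electrode = profiles[[n]]$max_electrode)
    })
    write_tsv(do.call(rbind, rows), file.path(config$out_dir, "components.tsv"))
    res$matching <- mt
    summary$characterize <- list(matched = sum(!is.na(mt$assignment)),
                                 mean_distance = mean(mt$distances, na.rm = TRUE))
  }

  if ("coupling" %in% config$stages && !is.null(profiles)) {
    pipeline_log(config$out_dir, "coupling", "theta-gamma modulation index")
    fs <- session$recording$fs
    theta <- theta_reference(session$recording, config$theta_band)
    th_phase <- analytic_phase_amp(bandpass(theta$trace, fs, config$theta_band))$phase
    states <- list(hold = config$hold_window, pull = config$pull_window)
    rows <- list()
    for (n in seq_along(profiles)) for (bn in names(config$bands)) {
      env <- analytic_phase_amp(bandpass(profiles[[n]]$ic, fs,
                                         config$bands[[bn]]))$amplitude
      for (st in names(states)) {
        w <- states[[st]]
        ph_tr <- list(); env_tr <- list()
        for (on in session$events$pull_onsets) {
          i0 <- round((on + w[1] / 1000) * fs) + 1L
          i1 <- round((on + w[2] / 1000) * fs) + 1L
          if (i0 < 1L || i1 > length(env)) next
          ph_tr[[length(ph_tr) + 1L]] <- th_phase[i0:i1]
          env_tr[[length(env_tr) + 1L]] <- env[i0:i1]
        }
        cr <- surrogate_mi(ph_tr, env_tr, n_surr = config$n_surrogates,
                           seed = config$seed + 100L + 10L * n)
        rows[[length(rows) + 1L]] <- data.frame(
          ic = n, band = bn, state = st, mi = cr$mi, p = cr$p,
          significant = cr$significant,
          preferred_phase_deg = cr$preferred_phase_deg,
          n_trials = length(ph_tr))
      }
    }
    coupling <- do.call(rbind, rows)
    write_tsv(coupling, file.path(config$out_dir, "coupling.tsv"))
    res$coupling <- coupling
    summary$coupling <- list(n_significant = sum(coupling$significant))
  }

  if ("spikes" %in% config$stages && !is.null(profiles)) {
    pipeline_log(config$out_dir, "spikes", "phase locking")
    traces <- setNames(lapply(profiles, `[[`, "ic"),
                       sprintf("IC%d", seq_along(profiles)))
    lp <- locked_proportions(session$spikes, traces, session$recording$fs,
                             session$events, bands = config$bands,
                             hold_window = config$hold_window,
                             pull_window = config$pull_window,
                             min_spikes = config$min_spikes)
    if (!is.null(lp)) write_tsv(lp, file.path(config$out_dir, "spike_locking.tsv"))
    res$spike_locking <- lp
  }

  if ("reservoir" %in% config$stages && !is.null(profiles)) {
    fs <- session$recording$fs
    ics <- do.call(rbind, lapply(profiles, `[[`, "ic"))
    cond_results <- list(); labels_by_cond <- list()
    rp_args <- config$reservoir
    for (cond in config$conditions) {
      cname <- if (identical(cond, "all")) "all" else sprintf("IC%d", cond)
      pipeline_log(config$out_dir, "reservoir", sprintf("condition %s", cname))
      exp <- reservoir_experiment(ics, session$events, fs,
                                  condition = cond,
                                  params = do.call(reservoir_params, rp_args),
                                  n_epochs = config$n_epochs,
                                  seed = config$seed)
      cond_results[[cname]] <- exp
      if ("subtypes" %in% config$stages) {
        cls <- classify_population(exp$responses, attr(exp$responses, "time_ms"))
        labels_by_cond[[cname]] <- cls$label
        write_tsv(cls, file.path(config$out_dir,
                                 sprintf("subtypes_%s.tsv", cname)))
      }
    }
    res$reservoir <- cond_results
    summary$reservoir <- lapply(cond_results, function(e)
      list(nrmse = e$train$nrmse_train))
    if (length(labels_by_cond)) {
      fr <- population_fractions(labels_by_cond)
      write_tsv(cbind(data.frame(subtype = rownames(fr)), as.data.frame(fr)),
                file.path(config$out_dir, "subtype_fractions.tsv"))
      res$fractions <- fr
      summary$subtypes <- as.list(as.data.frame(fr))
    }
  }

  if (config$make_figures) pipeline_figures(config, res)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(c(res, list(summary = summary)))
}

#' Drive the reservoir with component inputs and train it on the lever
#'
#' Conditions the component traces (10 Hz low-pass, normalization to
#' `[-1, 1]`), cuts the 18 training segments (1 s before to 500 ms after each
#' pull onset) of inputs and lever target, FORCE-trains the readout, and
#' collects the trial-averaged normalized responses.
#'
#' @param ics Matrix components x time of reconstructed component traces.
#' @param events An [event_table()] carrying the lever trace.
#' @param fs Sampling rate of `ics` and the lever (Hz).
#' @param condition `"all"` (components assigned randomly, one per neuron) or
#'   a component index (all neurons driven by that component).
#' @param params A [reservoir_params()].
#' @param n_epochs FORCE epochs (default 10).
#' @param window Trial window in seconds (default `c(1.0, 0.5)`).
#' @param seed RNG seed.
#' @return List with `model` (trained), `train` (error curve and NRMSE),
#'   `responses` (neurons x time in `[0, 1]`), `inputs_trials`,
#'   `targets_trials`.
#' @export
reservoir_experiment <- function(ics, events, fs, condition = "all",
                                 params = reservoir_params(),
                                 n_epochs = 10L, window = c(1.0, 0.5),
                                 seed = 1L) {
  cfg <- if (identical(condition, "all")) input_config("one_random_ic_per_neuron")
         else input_config("single_ic", single_ic = as.integer(condition))
  params$N_I <- nrow(ics)
  inputs <- prepare_inputs(ics, fs, cfg)
  lever <- events$lever
  if (is.null(lever)) ll_stop("spec_error", "events must carry a lever trace")
  n_steps <- round((window[1] + window[2]) * 1000 / params$dt) + 1L
  time_ms <- (seq_len(n_steps) - 1L) * params$dt - window[1] * 1000
  inputs_trials <- list(); targets_trials <- list()
  for (on in events$pull_onsets) {
    i0 <- round((on - window[1]) * fs) + 1L
    i1 <- round((on + window[2]) * fs) + 1L
    if (i0 < 1L || i1 > ncol(inputs)) next
    seg <- inputs[, i0:i1, drop = FALSE]
    tgt <- lever[i0:i1]
    inp <- resample_inputs(seg, fs, params$dt, n_steps)
    attr(inp, "time_ms") <- time_ms
    inputs_trials[[length(inputs_trials) + 1L]] <- inp
    targets_trials[[length(targets_trials) + 1L]] <-
      approx((seq_along(tgt) - 1L) / fs * 1000, tgt,
             xout = time_ms - time_ms[1], rule = 2)$y
  }
  model <- reservoir_build(params, cfg, seed = seed)
  tr <- force_train(model, inputs_trials, targets_trials,
                    n_epochs = n_epochs, seed = seed + 1L)
  responses <- collect_responses(tr$model, inputs_trials)
  attr(responses, "time_ms") <- time_ms
  list(model = tr$model, train = tr[c("error_curve", "nrmse_train")],
       responses = responses, inputs_trials = inputs_trials,
       targets_trials = targets_trials)
}

# simple diagnostic figures (base graphics, PNG)
pipeline_figures <- function(config, res) {
  png_of <- function(name, expr, w = 900, h = 600) {
    grDevices::png(file.path(config$out_dir, name), width = w, height = h)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
  }
  if (!is.null(res$decomposition)) {
    dec <- res$decomposition
    png_of("loadings.png", {
      graphics::matplot(dec$V, dec$depths, type = "b", pch = 16,
                        ylim = rev(range(dec$depths)),
                        xlab = "voltage loading (a.u.)", ylab = "depth (um)")
      graphics::legend("topright", legend = sprintf("IC%d", seq_len(ncol(dec$V))),
                       col = seq_len(ncol(dec$V)), lty = seq_len(ncol(dec$V)))
    })
  }
  if (!is.null(res$fractions)) {
    png_of("subtype_fractions.png",
           graphics::barplot(res$fractions, beside = TRUE,
                             legend.text = rownames(res$fractions),
                             ylab = "population fraction"))
  }
  invisible(NULL)
}
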