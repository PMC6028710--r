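# Rule-based classification of trial-averaged responses into functional
# subtypes (hold-related/movement-off, movement-related, pre-movement,
# post-movement, others) and circular activation-time sorting.

SUBTYPE_LEVELS <- c("Hold-related/Movement-off", "Movement-related",
                    "Pre-movement", "Post-movement", "Others")

#' Subtype classification rules
#'
#' @param baseline_window Baseline window (ms relative to pull onset) used for
#'   the per-neuron mean and SD (default 1000-250 ms before onset).
#' @param threshold_sd Phasic threshold in baseline SDs (default 3).
#' @param min_duration_ms Minimum supra/infra-threshold run length (default
#'   60 ms).
#' @param premove_start_before_ms Pre-movement epochs must start earlier than
#'   this many ms before onset (default 500).
#' @param premove_drop_frac Pre-movement activity must drop below this
#'   fraction of its peak after onset (default 0.5).
#' @param postmove_deadline_ms Post-movement epochs must end within this many
#'   ms of onset (default 350).
#' @param movement_window Window (ms) operationalizing "during movement"
#'   (default the pull window, -200 to +300 ms).
#' @return Object of class `subtype_rules`.
#' @export
subtype_rules <- function(baseline_window = c(-1000, -250), threshold_sd = 3,
                          min_duration_ms = 60, premove_start_before_ms = 500,
                          premove_drop_frac = 0.5, postmove_deadline_ms = 350,
                          movement_window = c(-200, 300)) {
  structure(list(baseline_window = baseline_window, threshold_sd = threshold_sd,
                 min_duration_ms = min_duration_ms,
                 premove_start_before_ms = premove_start_before_ms,
                 premove_drop_frac = premove_drop_frac,
                 postmove_deadline_ms = postmove_deadline_ms,
                 movement_window = movement_window),
            class = "subtype_rules")
}

# contiguous TRUE runs as (start_idx, end_idx) pairs
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect phasic epochs in normalized responses
#'
#' Phasic activity is a contiguous run of at least `min_duration_ms` during
#' which the response exceeds the baseline mean by more than
#' `threshold_sd` baseline SDs (positive epochs) or falls below it by the same
#' margin (negative epochs). Neurons with a flat baseline (SD = 0) are flagged
#' non-classifiable.
#'
#' @param response Matrix neurons x time of trial-averaged, min-max-normalized
#'   responses (a single neuron may be given as a vector).
#' @param time_ms Time axis (ms relative to pull onset) spanning
#'   `[-1000, +500]`.
#' @param rules A [subtype_rules()].
#' @return List, one element per neuron: a data frame of epochs (`sign`,
#'   `start_ms`, `end_ms`, `peak`) or `NULL` when none; attribute
#'   `non_classifiable` (logical per neuron).
#' @export
detect_phasic <- function(response, time_ms, rules = subtype_rules()) {
  if (is.null(dim(response))) response <- matrix(response, nrow = 1L)
  stopifnot(ncol(response) == length(time_ms))
  dt <- mean(diff(time_ms))
  min_len <- ceiling(rules$min_duration_ms / dt)
  bl <- time_ms >= rules$baseline_window[1] & time_ms <= rules$baseline_window[2]
  out <- vector("list", nrow(response))
  nc <- logical(nrow(response))
  for (i in seq_len(nrow(response))) {
    r <- response[i, ]
    mu <- mean(r[bl]); sg <- sd(r[bl])
    if (!is.finite(sg) || sg == 0) { nc[i] <- TRUE; next }
    eps <- list()
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) r > mu + rules$threshold_sd * sg
              else r < mu - rules$threshold_sd * sg
      rr <- runs_of(mask)
      if (!nrow(rr)) next
      keep <- (rr[, "end"] - rr[, "start"] + 1L) >= min_len
      rr <- rr[keep, , drop = FALSE]
      for (k in seq_len(nrow(rr))) {
        seg <- r[rr[k, 1]:rr[k, 2]]
        eps[[length(eps) + 1L]] <- data.frame(
          sign = sgn, start_ms = time_ms[rr[k, 1]], end_ms = time_ms[rr[k, 2]],
          peak = if (sgn > 0) max(seg) else min(seg))
      }
    }
    if (length(eps)) out[[i]] <- do.call(rbind, eps)
  }
  attr(out, "non_classifiable") <- nc
  out
}

#' Classify one neuron's epochs into a functional subtype
#'
#' Deterministic precedence: pre-movement (positive epoch starting earlier
#' than 500 ms before onset and dropping below half its peak after onset),
#' then post-movement (positive epoch starting at or after onset and ending
#' within 350 ms), then movement-related (positive epoch overlapping the
#' movement window), then hold-related/movement-off (negative epoch
#' overlapping the movement window; the two are not distinguished), then
#' others. Total: every neuron receives a label.
#'
#' @param epochs Epoch data frame from [detect_phasic()] (or `NULL`).
#' @param response The neuron's normalized response vector.
#' @param time_ms Time axis (ms).
#' @param rules A [subtype_rules()].
#' @return One of the subtype labels (character).
#' @export
classify <- function(epochs, response, time_ms, rules = subtype_rules()) {
  if (is.null(epochs) || !nrow(epochs)) return("Others")
  pos <- epochs[epochs$sign > 0, , drop = FALSE]
  neg <- epochs[epochs$sign < 0, , drop = FALSE]
  after <- time_ms > 0
  mw <- rules$movement_window
  overlaps_mv <- function(e) e$start_ms <= mw[2] & e$end_ms >= mw[1]
  if (nrow(pos)) {
    for (k in seq_len(nrow(pos))) {
      e <- pos[k, ]
      if (e$start_ms < -rules$premove_start_before_ms &&
          any(after) &&
          min(response[after]) < rules$premove_drop_frac * e$peak)
        return("Pre-movement")
    }
    for (k in seq_len(nrow(pos))) {
      e <- pos[k, ]
      if (e$start_ms >= 0 && e$end_ms <= rules$postmove_deadline_ms)
        return("Post-movement")
    }
    if (any(overlaps_mv(pos))) return("Movement-related")
  }
  if (nrow(neg) && any(overlaps_mv(neg)))
    return("Hold-related/Movement-off")
  "Others"
}

#' Circular activation time of a response
#'
#' Amplitude-weighted circular mean of the response's timing on the
#' `[-1000, +500]` ms segment, using `T = 750` two-millisecond bins (bin `t'`
#' maps to `2 t' - 1000` ms):
#' `t_hat = (T/pi) * Arg[ sum_t' rbar(t') exp(i 2 pi t' / T) ] - 1000`,
#' wrapped into `(-1000, +500]`. A point-mass response returns its bin time
#' exactly, and circularly shifting the response shifts `t_hat` accordingly.
#'
#' @param response Non-negative response, either already on the `T`-bin grid
#'   or on an arbitrary peri-onset grid given by `time_ms` (then binned).
#' @param time_ms Time axis (ms) when `response` is not already `T` bins.
#' @param T_bins Number of 2-ms bins (default 750).
#' @return Activation time in ms, in `(-1000, +500]`.
#' @export
activation_time <- function(response, time_ms = NULL, T_bins = 750L) {
  if (any(response < 0)) ll_stop("spec_error", "response must be non-negative")
  if (length(response) != T_bins) {
    if (is.null(time_ms))
      ll_stop("spec_error", "time_ms required to bin the response")
    bin <- pmin(pmax(floor((time_ms + 1000) / 2) + 1L, 1L), T_bins)
    rbar <- vapply(seq_len(T_bins), function(b) {
      v <- response[bin == b]
      if (length(v)) mean(v) else 0
    }, numeric(1))
  } else rbar <- response
  tot <- sum(rbar)
  if (tot <= 0) ll_stop("undefined_error", "all-zero response has no activation time")
  tp <- seq_len(T_bins)
  z <- sum(rbar * exp(1i * 2 * pi * tp / T_bins)) / tot
  t_hat <- T_bins / pi * Arg(z) - 1000
  if (t_hat <= -1000) t_hat <- t_hat + 2 * T_bins
  if (t_hat > 500) t_hat <- t_hat - 2 * T_bins
  t_hat
}

#' Classify and sort a population of responses
#'
#' @param response Matrix neurons x time from [collect_responses()].
#' @param time_ms Time axis (ms relative to pull onset).
#' @param rules A [subtype_rules()].
#' @return Data frame with one row per neuron: `neuron`, `label`,
#'   `t_hat` (ms; NA for all-zero responses), `rank` (serial order of
#'   activation time).
#' @export
classify_population <- function(response, time_ms, rules = subtype_rules()) {
  eps <- detect_phasic(response, time_ms, rules)
  nc <- attr(eps, "non_classifiable")
  labels <- vapply(seq_len(nrow(response)), function(i) {
    if (nc[i]) "Others"
    else classify(eps[[i]], response[i, ], time_ms, rules)
  }, character(1))
  t_hat <- vapply(seq_len(nrow(response)), function(i) {
    if (sum(response[i, ]) <= 0) NA_real_
    else activation_time(response[i, ], time_ms)
  }, numeric(1))
  data.frame(neuron = seq_len(nrow(response)),
             label = factor(labels, levels = SUBTYPE_LEVELS),
             t_hat = t_hat,
             rank = rank(t_hat, ties.method = "first", na.last = "keep"))
}

#' Subtype fractions per input condition
#'
#' @param labels_by_condition Named list; each element the label vector (or
#'   factor) of one input condition's classified population.
#' @return Matrix subtypes x conditions of fractions, each column summing
#'   to 1.
#' @export
population_fractions <- function(labels_by_condition) {
  if (!length(labels_by_condition))
    ll_stop("spec_error", "need at least one classified population")
  cols <- lapply(labels_by_condition, function(l) {
    if (!length(l)) ll_stop("spec_error", "empty population")
    tab <- table(factor(l, levels = SUBTYPE_LEVELS))
    as.numeric(tab) / sum(tab)
  })
  out <- do.call(cbind, cols)
  rownames(out) <- SUBTYPE_LEVELS
  colnames(out) <- names(labels_by_condition)
  out
}
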