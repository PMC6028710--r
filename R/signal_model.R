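# Core data containers for laminar recordings, behavioral events and spike
# trains, plus the flat-file I/O used by the pipeline. Storage conventions:
# voltages in mV, times in seconds on disk; analysis windows elsewhere in the
# package are quoted in milliseconds. Depth increases downward from the pia.

#' Laminar multi-channel LFP recording
#'
#' Container for a channels x time voltage matrix recorded along a linear
#' electrode array inserted through the cortical depth. Channel depths must be
#' equally spaced (the current-source-density operators assume a uniform grid).
#'
#' @param samples Numeric matrix, channels x time, voltage in mV.
#' @param depths Numeric vector of per-channel cortical depths in micrometers,
#'   strictly increasing and equally spaced; depth grows from pia downward.
#' @param fs Sampling rate in Hz.
#'
#' @return An object of class `laminar_recording` with fields `samples`,
#'   `depths`, `fs` and the inter-electrode spacing `h` (um).
#' @export
laminar_recording <- function(samples, depths, fs) {
  if (!is.matrix(samples) || !is.numeric(samples))
    ll_stop("validation_error", "samples must be a numeric matrix (channels x time)")
  if (nrow(samples) < 3L)
    ll_stop("validation_error", "at least 3 channels are required (CSD needs interior points)")
  if (ncol(samples) < 1L)
    ll_stop("validation_error", "samples matrix has no time points")
  if (anyNA(samples) || !all(is.finite(samples)))
    ll_stop("validation_error", "samples contain NaN/Inf values")
  if (!is.numeric(depths) || length(depths) != nrow(samples))
    ll_stop("validation_error", "depths must match the number of channels")
  dd <- diff(depths)
  if (any(dd <= 0))
    ll_stop("validation_error", "depths must be strictly increasing")
  if (max(dd) - min(dd) > 1e-6 * mean(dd))
    ll_stop("validation_error", "depths must be equally spaced")
  if (!is_number(fs) || fs <= 0)
    ll_stop("validation_error", "fs must be a positive number")
  structure(
    list(samples = samples, depths = as.numeric(depths), fs = as.numeric(fs),
         h = mean(dd)),
    class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf(
    "<laminar_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  depths: %g..%g um, spacing %g um\n",
              min(x$depths), max(x$depths), x$h))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [laminar_recording()].
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Behavioral event table
#'
#' Lever-pull onsets with reward flags and, optionally, the lever-position
#' trace. Onsets must leave at least 1 s of recording before and 0.5 s after
#' each event so that the peri-movement analysis window fits.
#'
#' @param pull_onsets Strictly increasing event times in seconds.
#' @param rewarded Logical vector, one flag per event (default all `TRUE`).
#' @param lever Optional numeric lever-position trace (normalized displacement).
#' @param fs_lever Sampling rate of `lever` in Hz.
#' @param duration_s Optional recording duration; when given, the pre/post
#'   margins of every onset are validated against it.
#' @return An object of class `event_table`.
#' @export
event_table <- function(pull_onsets, rewarded = NULL, lever = NULL,
                        fs_lever = NULL, duration_s = NULL) {
  if (length(pull_onsets) < 1L || !is.numeric(pull_onsets))
    ll_stop("validation_error", "pull_onsets must be a non-empty numeric vector")
  if (is.unsorted(pull_onsets, strictly = TRUE))
    ll_stop("validation_error", "pull_onsets must be strictly increasing")
  if (is.null(rewarded)) rewarded <- rep(TRUE, length(pull_onsets))
  if (length(rewarded) != length(pull_onsets))
    ll_stop("validation_error", "rewarded must have one flag per onset")
  if (!is.null(duration_s)) {
    if (any(pull_onsets < 1) || any(pull_onsets + 0.5 > duration_s))
      ll_stop("validation_error",
              "every onset needs >= 1 s pre-margin and >= 0.5 s post-margin inside the recording")
  }
  if (!is.null(lever) && is.null(fs_lever))
    ll_stop("validation_error", "fs_lever is required when a lever trace is given")
  structure(
    list(pull_onsets = as.numeric(pull_onsets), rewarded = as.logical(rewarded),
         lever = lever, fs_lever = fs_lever),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d lever pulls (%d rewarded)%s\n",
              length(x$pull_onsets), sum(x$rewarded),
              if (!is.null(x$lever)) sprintf(", lever trace @ %g Hz", x$fs_lever) else ""))
  invisible(x)
}

#' Set of sorted spike trains
#'
#' One entry per unit: spike times plus layer (`superficial`/`deep`) and
#' cell-class (`RS` regular-spiking / `FS` fast-spiking) labels, as produced by
#' spike-width classification.
#'
#' @param units A list; each element a list with `times` (sorted spike times,
#'   s), `layer`, `cell_class`, and optionally `id`.
#' @param duration_s Optional recording duration for span validation.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(units, duration_s = NULL) {
  if (!is.list(units) || length(units) == 0L)
    ll_stop("validation_error", "units must be a non-empty list")
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (is.null(u$times) || !is.numeric(u$times))
      ll_stop("validation_error", sprintf("unit %d has no numeric spike times", i))
    if (is.unsorted(u$times))
      ll_stop("validation_error", sprintf("unit %d spike times are not sorted", i))
    if (!is.null(duration_s) && length(u$times) &&
        (min(u$times) < 0 || max(u$times) > duration_s))
      ll_stop("validation_error", sprintf("unit %d has spikes outside the recording span", i))
    if (!u$layer %in% c("superficial", "deep"))
      ll_stop("validation_error", sprintf("unit %d layer must be 'superficial' or 'deep'", i))
    if (!u$cell_class %in% c("RS", "FS"))
      ll_stop("validation_error", sprintf("unit %d cell_class must be 'RS' or 'FS'", i))
    if (is.null(u$id)) units[[i]]$id <- sprintf("u%02d", i)
  }
  structure(list(units = units), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$units, function(u) length(u$times), integer(1))
  cat(sprintf("<spike_train_set> %d units, %d spikes total\n",
              length(x$units), sum(n)))
  invisible(x)
}

# Recording I/O --------------------------------------------------------------
# Flat float32 channel-major binary plus a JSON sidecar carrying fs, depths
# and units; keeps fixtures diff-able and language-neutral.

sidecar_path <- function(path) sub("\\.bin$", ".json", path)

#' Write a laminar recording to disk
#'
#' Stores samples as channel-major little-endian float32 in `<path>.bin` with a
#' JSON sidecar `<path>.json` holding `fs`, `depths`, `units` and the matrix
#' shape.
#'
#' @param rec A [laminar_recording()].
#' @param path Output path for the binary file (`.bin` appended if missing).
#' @return The path of the binary file, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "laminar_recording"))
    ll_stop("validation_error", "rec must be a laminar_recording")
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  dir <- dirname(path)
  if (!dir.exists(dir))
    ll_stop("io_error", sprintf("directory does not exist: %s", dir))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.vector(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(format = "laminarLFP-recording-v1",
               n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               fs = rec$fs, depths = rec$depths, units = "mV",
               depth_units = "um", dtype = "float32", order = "channel-major")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a laminar recording from disk
#'
#' Inverse of [write_recording()]. Fails with a classed `format_error` when the
#' sidecar is missing or inconsistent with the binary payload.
#'
#' @param path Path to the `.bin` file written by [write_recording()].
#' @return A [laminar_recording()].
#' @export
read_recording <- function(path) {
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  if (!file.exists(path))
    ll_stop("io_error", sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    ll_stop("format_error", sprintf("missing JSON sidecar: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("n_channels", "n_samples", "fs", "depths")
  if (!all(need %in% names(meta)))
    ll_stop("format_error", "sidecar lacks required fields")
  n_val <- file.size(path) / 4
  if (n_val != meta$n_channels * meta$n_samples)
    ll_stop("format_error", sprintf(
      "binary holds %d float32 values but sidecar claims %d x %d",
      n_val, meta$n_channels, meta$n_samples))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
  samples <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  laminar_recording(samples, meta$depths, meta$fs)
}

# Event / spike / lever TSV I/O ----------------------------------------------

#' Write an event table (and lever trace) as TSV
#' @param events An [event_table()].
#' @param dir Output directory; writes `events.tsv` and, when a lever trace is
#'   present, `lever.tsv`.
#' @return `dir`, invisibly.
#' @export
write_events <- function(events, dir) {
  df <- data.frame(onset_s = events$pull_onsets,
                   rewarded = as.integer(events$rewarded))
  write.table(df, file.path(dir, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(events$lever)) {
    lv <- data.frame(
      time_s = (seq_along(events$lever) - 1) / events$fs_lever,
      position = events$lever)
    write.table(lv, file.path(dir, "lever.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read an event table written by [write_events()]
#' @param dir Directory holding `events.tsv` (and optionally `lever.tsv`).
#' @param duration_s Optional recording duration for margin validation.
#' @return An [event_table()].
#' @export
read_events <- function(dir, duration_s = NULL) {
  f <- file.path(dir, "events.tsv")
  if (!file.exists(f)) ll_stop("io_error", sprintf("no such file: %s", f))
  df <- read.delim(f)
  lever <- NULL; fs_lever <- NULL
  lf <- file.path(dir, "lever.tsv")
  if (file.exists(lf)) {
    lv <- read.delim(lf)
    lever <- lv$position
    fs_lever <- 1 / mean(diff(lv$time_s))
  }
  event_table(df$onset_s, as.logical(df$rewarded), lever = lever,
              fs_lever = fs_lever, duration_s = duration_s)
}

#' Write a spike-train set as TSV
#' @param spikes A [spike_train_set()].
#' @param dir Output directory; writes `spikes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_spikes <- function(spikes, dir) {
  rows <- do.call(rbind, lapply(spikes$units, function(u)
    if (length(u$times))
      data.frame(unit_id = u$id, time_s = u$times, layer = u$layer,
                 cell_class = u$cell_class)
    else NULL))
  write.table(rows, file.path(dir, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a spike-train set written by [write_spikes()]
#' @param dir Directory holding `spikes.tsv`.
#' @param duration_s Optional recording duration for span validation.
#' @return A [spike_train_set()].
#' @export
read_spikes <- function(dir, duration_s = NULL) {
  f <- file.path(dir, "spikes.tsv")
  if (!file.exists(f)) ll_stop("io_error", sprintf("no such file: %s", f))
  df <- read.delim(f)
  units <- lapply(split(df, df$unit_id), function(d)
    list(id = d$unit_id[1], times = sort(d$time_s),
         layer = d$layer[1], cell_class = d$cell_class[1]))
  spike_train_set(unname(units), duration_s = duration_s)
}

# Trial segmentation ----------------------------------------------------------

#' Cut peri-event trial windows out of a recording
#'
#' Aligns a window around every lever-pull onset and stacks the snippets into a
#' trials x channels x time array. The sample at time 0 (the onset) is included
#' in the post-window, so a `(pre_s, post_s)` window at sampling rate `fs`
#' yields `round(pre_s*fs) + round(post_s*fs) + 1` samples.
#'
#' @param rec A [laminar_recording()].
#' @param events An [event_table()].
#' @param window Numeric pair `(pre_s, post_s)`, both non-negative, in seconds.
#' @return Array trials x channels x time with attributes `time_ms` (peri-onset
#'   time axis in ms) and `fs`.
#' @export
segment_trials <- function(rec, events, window = c(1.0, 0.5)) {
  if (length(window) != 2L || any(window < 0))
    ll_stop("validation_error", "window must be c(pre_s, post_s), both >= 0")
  fs <- rec$fs
  n_pre <- round(window[1] * fs)
  n_post <- round(window[2] * fs)
  n_t <- n_pre + n_post + 1L
  onset_idx <- round(events$pull_onsets * fs) + 1L
  first <- onset_idx - n_pre
  last <- onset_idx + n_post
  if (any(first < 1L) || any(last > ncol(rec$samples)))
    ll_stop("boundary_error", "a trial window falls outside the recording span")
  out <- array(NA_real_,
               dim = c(length(onset_idx), nrow(rec$samples), n_t))
  for (i in seq_along(onset_idx))
    out[i, , ] <- rec$samples[, first[i]:last[i], drop = FALSE]
  attr(out, "time_ms") <- (seq_len(n_t) - 1L - n_pre) / fs * 1000
  attr(out, "fs") <- fs
  out
}
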