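#' Epoched multichannel ERP data
#'
#' An `epoch_set` bundles a numeric tensor of epoched EEG/EOG (and
#' optionally gaze) data with its channel labels, sampling rate, epoch
#' window and a tibble of per-trial metadata.  Samples live on a
#' half-open `[start, end)` millisecond grid: sample `i` sits at
#' `start + (i - 1) * 1000 / srate` ms.
#'
#' @param data Numeric array `trials x channels x samples` (microvolts
#'   for EEG/EOG channels, degrees for gaze channels).
#' @param channels Character channel labels, one per slice of dim 2.
#' @param srate Sampling rate in Hz.
#' @param window Epoch window `c(start, end)` in ms relative to
#'   memory-array onset.
#' @param trials Tibble of per-trial metadata (one row per slice of
#'   dim 1); for CDA analyses it must contain `participant`,
#'   `stim_type`, `set_size` and `cue_side`.
#'
#' @return An object of class `epoch_set`.
#' @seealso [gen_erp_epochs()], [compute_cda()]
#' @export
epoch_set <- function(data, channels, srate, window, trials) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels))
    abort("dim(data)[2] must equal length(channels)")
  n_samp <- round((window[2] - window[1]) * srate / 1000)
  if (dim(data)[3] != n_samp)
    abort(sprintf("dim(data)[3] = %d but window/srate imply %d samples",
                  dim(data)[3], n_samp))
  trials <- as_tibble(trials)
  if (nrow(trials) != dim(data)[1])
    abort("trials metadata must have one row per epoch")
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, channels = channels, srate = srate,
                 window = window, trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %g Hz, window [%g, %g) ms\n", x$srate,
              x$window[1], x$window[2]))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = " ")))
  meta <- intersect(c("participant", "stim_type", "set_size", "cue_side"),
                    names(x$trials))
  if (length(meta) > 0L)
    cat(sprintf("  metadata: %s\n", paste(meta, collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Sample times of an epoch set
#'
#' @param x An [epoch_set()].
#' @return Numeric vector of sample times in ms.
#' @export
epoch_times <- function(x) {
  x$window[1] + (seq_len(dim(x$data)[3]) - 1) * 1000 / x$srate
}

#' Subset an epoch set by trial
#'
#' @param x An [epoch_set()].
#' @param i Logical or integer trial index.
#' @return An [epoch_set()] containing the selected trials.
#' @export
filter_epochs <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$channels, x$srate, x$window,
            x$trials[i, ])
}

eeg_channel_idx <- function(x) {
  which(!(x$channels %in% c(eog_channels, gaze_channels)))
}

#' Write / read an epoch set as a plain-text directory
#'
#' The on-disk layout is a directory with `data.csv` (one row per
#' trial x channel, samples as columns), `channels.json` (channel
#' labels, sampling rate, window) and `trials.csv` (per-trial metadata).
#'
#' @param x An [epoch_set()].
#' @param dir Directory path (created if needed).
#' @return `write_epoch_set()` returns `dir` invisibly;
#'   `read_epoch_set()` returns an [epoch_set()].
#' @export
write_epoch_set <- function(x, dir) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  dt <- data.table::data.table(trial = rep(seq_len(d[1]), each = d[2]),
                               channel = rep(x$channels, d[1]))
  dt <- cbind(dt, data.table::as.data.table(flat))
  data.table::fwrite(dt, file.path(dir, "data.csv"))
  jsonlite::write_json(list(channels = x$channels, srate = x$srate,
                            window = x$window),
                       file.path(dir, "channels.json"), auto_unbox = FALSE,
                       digits = NA)
  readr::write_csv(x$trials, file.path(dir, "trials.csv"))
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "channels.json"),
                              simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "data.csv"))
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE)
  n_chan <- length(meta$channels)
  n_trial <- nrow(dt) / n_chan
  flat <- as.matrix(dt[, -(1:2)])
  arr <- aperm(array(flat, dim = c(n_chan, n_trial, ncol(flat))), c(2, 1, 3))
  epoch_set(arr, meta$channels, meta$srate, meta$window, trials)
}
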