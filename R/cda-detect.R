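# sliding-window primitives ---------------------------------------------------
#
# Windows are positioned on sample indices with a half-open convention:
# a window of `w` samples starting at sample `s` covers s .. s + w - 1,
# starts advance by `step` samples, and a partial trailing window is
# skipped.  The step detectors compare the mean of the first half of
# each window with the mean of the second half (for odd `w` the middle
# sample belongs to neither half).

window_starts <- function(n_samp, w, step) {
  if (w > n_samp) return(integer(0))
  seq(1L, n_samp - w + 1L, by = step)
}

# max |mean(second half) - mean(first half)| over all windows
max_half_diff <- function(v, w, step) {
  starts <- window_starts(length(v), w, step)
  if (length(starts) == 0L) return(0)
  half <- w %/% 2L
  cs <- c(0, cumsum(v))
  first <- (cs[starts + half] - cs[starts]) / half
  second <- (cs[starts + w] - cs[starts + w - half]) / half
  max(abs(second - first))
}

# max peak-to-peak amplitude over all windows
max_p2p <- function(v, w, step) {
  starts <- window_starts(length(v), w, step)
  if (length(starts) == 0L) return(0)
  max(vapply(starts, function(s) {
    seg <- v[s:(s + w - 1L)]
    max(seg) - min(seg)
  }, 1.0))
}

ms_to_samples <- function(ms, srate) as.integer(round(ms * srate / 1000))

apply_channels <- function(x, channel_idx, fun) {
  n_trial <- dim(x$data)[1]
  vapply(seq_len(n_trial), function(tr) {
    any(vapply(channel_idx, function(ch) fun(x$data[tr, ch, ]), TRUE))
  }, TRUE)
}

# detectors -------------------------------------------------------------------

#' Ocular artifact detection on the EOG channels
#'
#' Flags a trial when the absolute voltage on VEOG or HEOG exceeds
#' `abs_limit` anywhere in the epoch, or when step-like activity —
#' the difference between the mean of the first and second half of a
#' sliding window — exceeds `step_limit` within a `window_ms` window
#' advanced in `step_ms` steps.
#'
#' @param x An [epoch_set()] containing VEOG and HEOG channels (if they
#'   are absent but gaze channels exist, the caller should rely on
#'   [detect_gaze()]; if neither is present this is an error).
#' @param abs_limit Absolute-voltage threshold in microvolts.
#' @param step_limit Half-window mean-difference threshold in
#'   microvolts.
#' @param window_ms,step_ms Sliding-window length and advance in ms.
#'
#' @return A tibble with columns `trial`, `eog_abs`, `eog_step`.
#' @export
detect_eog <- function(x, abs_limit = 50, step_limit = 30,
                       window_ms = 100, step_ms = 10) {
  stopifnot(inherits(x, "epoch_set"))
  idx <- which(x$channels %in% eog_channels)
  if (length(idx) == 0L) {
    if (any(x$channels %in% gaze_channels))
      abort("no EOG channels; use detect_gaze() for ocular rejection")
    abort("neither EOG nor gaze channels present: ocular artifacts cannot be screened")
  }
  w <- ms_to_samples(window_ms, x$srate)
  s <- ms_to_samples(step_ms, x$srate)
  tibble(trial = seq_len(dim(x$data)[1]),
         eog_abs = apply_channels(x, idx, function(v) any(abs(v) > abs_limit)),
         eog_step = apply_channels(x, idx, function(v)
           max_half_diff(v, w, s) > step_limit))
}

#' Gaze-position artifact detection
#'
#' Step-style sliding-window detector on the x and y gaze coordinates:
#' a trial is flagged when the half-window mean difference exceeds
#' `threshold_deg` within a `window_ms` window advanced in `step_ms`
#' steps.  Returns `NULL` with a message when no gaze channels are
#' present (ocular rejection then falls back to the EOG detectors).
#'
#' @inheritParams detect_eog
#' @param threshold_deg Threshold in degrees of visual angle.
#' @return A tibble with columns `trial` and `gaze`, or `NULL`.
#' @export
detect_gaze <- function(x, threshold_deg = 0.5, window_ms = 100, step_ms = 10) {
  stopifnot(inherits(x, "epoch_set"))
  idx <- which(x$channels %in% gaze_channels)
  if (length(idx) == 0L) {
    message("no gaze channels present; skipping gaze rejection")
    return(NULL)
  }
  w <- ms_to_samples(window_ms, x$srate)
  s <- ms_to_samples(step_ms, x$srate)
  tibble(trial = seq_len(dim(x$data)[1]),
         gaze = apply_channels(x, idx, function(v)
           max_half_diff(v, w, s) > threshold_deg))
}

#' Slow-drift detection by linear trend fitting
#'
#' Fits a least-squares line to each EEG channel of each epoch and flags
#' the trial when the magnitude of the fitted voltage change across the
#' whole epoch exceeds `slope_limit` microvolts and the line explains at
#' least `r2_min` of the channel variance.
#'
#' @inheritParams detect_eog
#' @param slope_limit Total fitted change threshold in microvolts.
#' @param r2_min Minimum R-squared of the linear fit.
#' @return Logical vector, one flag per trial.
#' @export
detect_drift <- function(x, slope_limit = 75, r2_min = 0.3) {
  stopifnot(inherits(x, "epoch_set"))
  n_samp <- dim(x$data)[3]
  t0 <- seq_len(n_samp) - (n_samp + 1) / 2          # centred time index
  sxx <- sum(t0^2)
  apply_channels(x, eeg_channel_idx(x), function(v) {
    slope <- sum(t0 * (v - mean(v))) / sxx
    change <- abs(slope) * (n_samp - 1)
    if (change <= slope_limit) return(FALSE)
    ssv <- sum((v - mean(v))^2)
    if (ssv == 0) return(FALSE)
    r2 <- slope^2 * sxx / ssv
    r2 >= r2_min
  })
}

#' Peak-to-peak artifact detection
#'
#' Flags a trial when the peak-to-peak amplitude of any EEG channel
#' exceeds `limit` microvolts within a `window_ms` sliding window
#' advanced in `step_ms` steps.
#'
#' @inheritParams detect_eog
#' @param limit Peak-to-peak threshold in microvolts.
#' @return Logical vector, one flag per trial.
#' @export
detect_p2p <- function(x, limit = 75, window_ms = 200, step_ms = 100) {
  stopifnot(inherits(x, "epoch_set"))
  w <- ms_to_samples(window_ms, x$srate)
  s <- ms_to_samples(step_ms, x$srate)
  apply_channels(x, eeg_channel_idx(x), function(v) max_p2p(v, w, s) > limit)
}

#' Extreme-value, step and flatline detection on the EEG channels
#'
#' Three sub-detectors over all EEG channels: absolute voltage exceeding
#' `abs_limit` microvolts anywhere in the epoch; step-like voltage
#' changes whose half-window mean difference exceeds `step_limit` within
#' a `window_ms` window advanced in `step_ms` steps; and flatline
#' signals, defined as zero variance over `flat_span_ms` (by default the
#' whole epoch).
#'
#' @inheritParams detect_eog
#' @param abs_limit Absolute-voltage threshold in microvolts.
#' @param step_limit Half-window mean-difference threshold in
#'   microvolts.
#' @param flat_span_ms Span over which zero variance counts as a
#'   flatline; `NULL` means the whole epoch.
#' @return A tibble with columns `trial`, `abs_volt`, `eeg_step`,
#'   `flatline`.
#' @export
detect_abs_and_steps <- function(x, abs_limit = 100, step_limit = 60,
                                 window_ms = 150, step_ms = 10,
                                 flat_span_ms = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  idx <- eeg_channel_idx(x)
  w <- ms_to_samples(window_ms, x$srate)
  s <- ms_to_samples(step_ms, x$srate)
  n_samp <- dim(x$data)[3]
  flat_w <- if (is.null(flat_span_ms)) n_samp
            else min(n_samp, ms_to_samples(flat_span_ms, x$srate))
  tibble(trial = seq_len(dim(x$data)[1]),
         abs_volt = apply_channels(x, idx, function(v)
           any(abs(v) > abs_limit)),
         eeg_step = apply_channels(x, idx, function(v)
           max_half_diff(v, w, s) > step_limit),
         flatline = apply_channels(x, idx, function(v) {
           if (flat_w >= length(v)) return(max(v) == min(v))
           starts <- window_starts(length(v), flat_w, flat_w)
           any(vapply(starts, function(st) {
             seg <- v[st:(st + flat_w - 1L)]
             max(seg) == min(seg)
           }, TRUE))
         }))
}

#' Run the full rule-based artifact rejection suite
#'
#' Applies every detector that its channels allow — EOG absolute voltage
#' and step, gaze steps (skipped when no gaze channels are recorded),
#' EEG drift, peak-to-peak, absolute voltage, EEG steps and flatline —
#' and marks a trial rejected when any detector flags it.
#'
#' @param x An [epoch_set()].
#' @param eog_abs_limit,eog_step_limit EOG thresholds in microvolts.
#' @param gaze_threshold_deg Gaze step threshold in degrees.
#' @param drift_slope_limit,drift_r2_min Drift-detector settings.
#' @param p2p_limit Peak-to-peak threshold in microvolts.
#' @param abs_limit,eeg_step_limit EEG extreme-value and step
#'   thresholds in microvolts.
#'
#' @return A tibble (one row per trial) with one logical column per
#'   detector plus `rejected`.
#' @export
reject_epochs <- function(x,
                          eog_abs_limit = 50, eog_step_limit = 30,
                          gaze_threshold_deg = 0.5,
                          drift_slope_limit = 75, drift_r2_min = 0.3,
                          p2p_limit = 75,
                          abs_limit = 100, eeg_step_limit = 60) {
  stopifnot(inherits(x, "epoch_set"))
  n_trial <- dim(x$data)[1]
  flags <- tibble(trial = seq_len(n_trial))
  has_eog <- any(x$channels %in% eog_channels)
  has_gaze <- any(x$channels %in% gaze_channels)
  if (!has_eog && !has_gaze)
    abort("neither EOG nor gaze channels present: ocular artifacts cannot be screened")
  if (has_eog) {
    flags <- left_join(flags,
                       detect_eog(x, eog_abs_limit, eog_step_limit),
                       by = "trial")
  } else {
    flags$eog_abs <- FALSE
    flags$eog_step <- FALSE
  }
  gz <- if (has_gaze) detect_gaze(x, gaze_threshold_deg) else NULL
  flags$gaze <- if (is.null(gz)) FALSE else gz$gaze
  flags$drift <- detect_drift(x, drift_slope_limit, drift_r2_min)
  flags$p2p <- detect_p2p(x, p2p_limit)
  flags <- left_join(flags, detect_abs_and_steps(x, abs_limit, eeg_step_limit),
                     by = "trial")
  flags$rejected <- flags |>
    select(-"trial") |>
    as.matrix() |>
    rowSums() > 0
  flags
}

#' Reject artifact trials and exclude high-rejection participants
#'
#' Runs [reject_epochs()], computes each participant's rejection rate,
#' excludes participants whose rate exceeds `max_rate` (the printed
#' 30%-of-trials rule), and returns the retained epochs together with
#' the per-trial flag table and per-participant bookkeeping.  Rejection
#' applies to EEG analyses only; the caller's behavioral trial table is
#' untouched.
#'
#' @param x An [epoch_set()] whose trial metadata contains
#'   `participant`.
#' @param max_rate Rejection-rate threshold above which a participant is
#'   excluded.
#' @param ... Threshold overrides passed to [reject_epochs()].
#'
#' @return An object of class `cda_rejection`: a list with `report`
#'   (per-trial flags joined to the trial metadata), `rates`
#'   (per-participant rejection rate and exclusion status), `epochs`
#'   (the retained [epoch_set()]), `retained_participants` and
#'   `excluded_participants`.
#' @export
reject_and_exclude <- function(x, max_rate = 0.30, ...) {
  stopifnot(inherits(x, "epoch_set"))
  require_columns(x$trials, "participant", "trial metadata")
  flags <- reject_epochs(x, ...)
  report <- bind_cols(x$trials["participant"], flags)
  rates <- report |>
    group_by(.data$participant) |>
    summarise(n_trials = n(), n_rejected = sum(.data$rejected),
              rate = .data$n_rejected / .data$n_trials, .groups = "drop") |>
    mutate(excluded = .data$rate > max_rate)
  excluded <- as.character(rates$participant[rates$excluded])
  retained <- as.character(rates$participant[!rates$excluded])
  if (length(retained) == 0L)
    abort("all participants exceed the rejection-rate threshold",
          class = "wmcda_all_excluded")
  keep <- !flags$rejected & !(as.character(x$trials$participant) %in% excluded)
  structure(list(report = report, rates = rates,
                 epochs = filter_epochs(x, keep),
                 retained_participants = retained,
                 excluded_participants = excluded,
                 max_rate = max_rate),
            class = "cda_rejection")
}

#' @export
print.cda_rejection <- function(x, ...) {
  cat(sprintf("<cda_rejection> %d/%d trials retained; %d participant(s) excluded (rate > %.0f%%)\n",
              sum(!x$report$rejected), nrow(x$report),
              length(x$excluded_participants), 100 * x$max_rate))
  cat(sprintf("  mean rejection rate among retained participants: %.1f%%\n",
              100 * mean(x$rates$rate[!x$rates$excluded])))
  invisible(x)
}

#' @rdname reject_and_exclude
#' @param x,object A `cda_rejection`.
#' @param ... Unused.
#' @method tidy cda_rejection
#' @export
tidy.cda_rejection <- function(x, ...) x$rates

#' @rdname reject_and_exclude
#' @method glance cda_rejection
#' @export
glance.cda_rejection <- function(x, ...) {
  tibble(n_trials = nrow(x$report),
         n_rejected = sum(x$report$rejected),
         mean_rate_retained = mean(x$rates$rate[!x$rates$excluded]),
         n_excluded = length(x$excluded_participants))
}
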