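#' Simulate lateralized ERP epochs with a CDA and injectable artifacts
#'
#' Generates an [epoch_set()] whose posterior electrodes carry a
#' sustained contralateral negativity relative to the cued hemifield,
#' with amplitude `slope_uv * min(set_size, k_plateau) + delta_uv`
#' microvolts per the simulator spec, on top of 1/f-shaped Gaussian
#' noise.  Artifact classes are injected at the spec's per-trial rates
#' with amplitudes at least 1.5 times their rule-based detection
#' thresholds, and each injection is recorded in the trial metadata as a
#' ground-truth label (`artifact_blink`, ..., `artifact_any`):
#'
#' * blink: 400-ms biphasic deflection on VEOG (peak 150 uV);
#' * saccade: sustained HEOG step of +/-60 uV (and a 1 degree gaze step
#'   when gaze channels are simulated);
#' * drift: linear ramp of 150 uV across the epoch on one EEG channel;
#' * muscle: 200-ms high-frequency burst, 150 uV peak-to-peak;
#' * step: instantaneous +/-120 uV DC shift on one EEG channel;
#' * flatline: one EEG channel replaced by a constant.
#'
#' @param spec An [erp_sim_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#'
#' @return An [epoch_set()]; `$trials` carries `participant`,
#'   `stim_type`, `set_size`, `cue_side`, and logical artifact labels.
#'
#' @examples
#' spec <- erp_sim_spec(n_participants = 2, n_trials = 4, noise_sd = 5)
#' epochs <- gen_erp_epochs(spec, seed = 3)
#' epochs
#' @export
gen_erp_epochs <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "erp_sim_spec"))
  withr::with_seed(as.integer(seed), {
    n_samp <- round((spec$window[2] - spec$window[1]) * spec$srate / 1000)
    times <- spec$window[1] + (seq_len(n_samp) - 1) * 1000 / spec$srate
    trials <- expand_grid(
      participant = participant_labels(spec$n_participants),
      stim_type = spec$stim_types,
      set_size = spec$set_sizes,
      trial = seq_len(spec$n_trials)) |>
      mutate(cue_side = sample(c("left", "right"), n(), replace = TRUE))
    n_trial <- nrow(trials)
    n_chan <- length(spec$channels)
    is_gaze <- spec$channels %in% gaze_channels
    is_eeg <- !(spec$channels %in% c(eog_channels, gaze_channels))

    arr <- array(0, dim = c(n_trial, n_chan, n_samp))
    if (spec$noise_sd > 0) {
      noise <- shaped_noise(n_samp, n_trial * sum(!is_gaze),
                            spec$noise_exponent) * spec$noise_sd
      arr[, !is_gaze, ] <- aperm(array(noise,
                                       dim = c(n_samp, sum(!is_gaze), n_trial)),
                                 c(3, 2, 1))
    }
    if (any(is_gaze))
      arr[, is_gaze, ] <- rnorm(n_trial * sum(is_gaze) * n_samp, 0, 0.05)

    # lateralized deflection: full amplitude from onset_ms, 100-ms rise
    envelope <- pmin(pmax((times - (spec$onset_ms - 100)) / 100, 0), 1)
    amp <- spec$slope_uv * pmin(trials$set_size,
                                spec$k_plateau[trials$stim_type]) +
      spec$delta_uv[trials$stim_type]
    right_hemi <- spec$channels %in% c("P4", "P8", "PO4", "PO8")
    left_hemi <- spec$channels %in% c("P3", "P7", "PO3", "PO7")
    contra_left <- trials$cue_side == "left"   # contra = right hemisphere
    signal <- outer(amp, envelope)             # n_trial x n_samp
    for (ch in which(right_hemi))
      arr[contra_left, ch, ] <- arr[contra_left, ch, ] + signal[contra_left, ]
    for (ch in which(left_hemi))
      arr[!contra_left, ch, ] <- arr[!contra_left, ch, ] + signal[!contra_left, ]

    labels <- inject_artifacts(arr, spec, times, is_eeg)
    trials <- bind_cols(trials, labels$labels)
    epoch_set(labels$arr, spec$channels, spec$srate, spec$window, trials)
  })
}

# columns of iid 1/f^a-shaped noise with unit RMS (in expectation)
shaped_noise <- function(n, ncols, exponent, chunk = 4000L) {
  if (ncols == 0L) return(matrix(numeric(0), n, 0))
  white <- matrix(rnorm(n * ncols), n, ncols)
  if (exponent == 0) return(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)                      # cycles per epoch, symmetric
  filt <- ifelse(f == 0, 0, f^(-exponent / 2))
  filt <- filt * sqrt(n / sum(filt^2))     # unit output variance
  out <- matrix(0, n, ncols)
  starts <- seq(1L, ncols, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, ncols)
    spec <- stats::mvfft(white[, idx, drop = FALSE]) * filt
    out[, idx] <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  }
  out
}

inject_artifacts <- function(arr, spec, times, is_eeg) {
  n_trial <- dim(arr)[1]
  n_samp <- dim(arr)[3]
  srate <- spec$srate
  veog <- match("VEOG", spec$channels)
  heog <- match("HEOG", spec$channels)
  gx <- match("GAZE_X", spec$channels)
  eeg_idx <- which(is_eeg)
  rates <- spec$artifact_rates
  lab <- tibble(
    artifact_blink = runif(n_trial) < rates[["blink"]],
    artifact_saccade = runif(n_trial) < rates[["saccade"]],
    artifact_drift = runif(n_trial) < rates[["drift"]],
    artifact_muscle = runif(n_trial) < rates[["muscle"]],
    artifact_step = runif(n_trial) < rates[["step"]],
    artifact_flatline = runif(n_trial) < rates[["flatline"]])

  blink_len <- round(0.4 * srate)                      # 400 ms
  blink_shape <- 150 * sin(2 * pi * seq_len(blink_len) / blink_len)
  burst_len <- round(0.2 * srate)                      # 200 ms
  burst <- 75 * sin(2 * pi * 60 * seq_len(burst_len) / srate) *
    sin(pi * seq_len(burst_len) / burst_len)           # windowed 60-Hz burst
  ramp <- seq(0, 150, length.out = n_samp)

  for (tr in seq_len(n_trial)) {
    if (lab$artifact_blink[tr]) {
      at <- sample.int(n_samp - blink_len, 1L)
      arr[tr, veog, at:(at + blink_len - 1L)] <-
        arr[tr, veog, at:(at + blink_len - 1L)] + blink_shape
    }
    if (lab$artifact_saccade[tr]) {
      at <- sample.int(n_samp - round(0.2 * srate), 1L)
      sgn <- sample(c(-1, 1), 1L)
      arr[tr, heog, at:n_samp] <- arr[tr, heog, at:n_samp] + sgn * 60
      if (!is.na(gx))
        arr[tr, gx, at:n_samp] <- arr[tr, gx, at:n_samp] + sgn * 1.0
    }
    if (lab$artifact_drift[tr]) {
      ch <- sample(eeg_idx, 1L)
      arr[tr, ch, ] <- arr[tr, ch, ] + sample(c(-1, 1), 1L) * ramp
    }
    if (lab$artifact_muscle[tr]) {
      ch <- sample(eeg_idx, 1L)
      at <- sample.int(n_samp - burst_len, 1L)
      arr[tr, ch, at:(at + burst_len - 1L)] <-
        arr[tr, ch, at:(at + burst_len - 1L)] + burst
    }
    if (lab$artifact_step[tr]) {
      ch <- sample(eeg_idx, 1L)
      at <- sample.int(n_samp - round(0.2 * srate), 1L)
      arr[tr, ch, at:n_samp] <- arr[tr, ch, at:n_samp] +
        sample(c(-1, 1), 1L) * 120
    }
    if (lab$artifact_flatline[tr]) {
      ch <- sample(eeg_idx, 1L)
      arr[tr, ch, ] <- 0
    }
  }
  lab$artifact_any <- Reduce(`|`, lab)
  list(arr = arr, labels = lab)
}
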