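#' Population specification for the dual-process recognition generator
#'
#' Describes a population of observers for the dual-process
#' signal-detection (DPSD) recognition task: per-condition population
#' means for recollection and familiarity, a shared set of ordered
#' confidence criteria, and between-participant standard deviations on
#' the transformed scales the generator samples on (probit for
#' recollection, identity for familiarity, an additive shift for the
#' criteria and a jitter on the log criterion increments).
#'
#' Defaults correspond to a six-item recognition study with three
#' blocked stimulus conditions (repeated colors `CLR_REP`, repeated
#' objects `OBJ_REP`, trial-unique objects `OBJ_UNI`), 31 participants
#' and 120 trials per condition, with population recollection and
#' familiarity set to typical fitted values for that design.
#'
#' @param conditions Character vector of condition labels.
#' @param mean_recollection Population recollection probability per
#'   condition, each in `[0, 1]`.
#' @param mean_familiarity Population familiarity strength per condition
#'   (standard-normal-distance units, the model's d-prime analogue).
#' @param criteria Population means of the five confidence criteria on
#'   the familiarity axis; strictly increasing.
#' @param sd_recollection Between-participant SD of recollection on the
#'   probit scale.
#' @param sd_familiarity Between-participant SD of familiarity.
#' @param sd_criterion_shift Between-participant SD of a common additive
#'   shift applied to all five criteria.
#' @param sd_log_increment Between-participant SD of the jitter on the
#'   log criterion increments.
#' @param n_participants,n_trials_per_condition Design size.
#' @param p_old Probability that a probe is old.
#' @param set_size Number of items in the memory array (metadata only).
#' @param seed Default random seed used by [gen_recognition_trials()].
#'
#' @return An object of class `dpsd_population_spec`.
#' @seealso [gen_recognition_trials()]
#' @export
dpsd_population_spec <- function(conditions = c("CLR_REP", "OBJ_REP", "OBJ_UNI"),
                                 mean_recollection = c(0.35, 0.35, 0.36),
                                 mean_familiarity = c(0.93, 0.91, 1.10),
                                 criteria = c(-0.4, 0.2, 0.8, 1.4, 2.0),
                                 sd_recollection = 0.2,
                                 sd_familiarity = 0.2,
                                 sd_criterion_shift = 0.15,
                                 sd_log_increment = 0.1,
                                 n_participants = 31,
                                 n_trials_per_condition = 120,
                                 p_old = 0.5,
                                 set_size = 6,
                                 seed = 1L) {
  if (!is.character(conditions) || length(conditions) < 1L)
    stop_field("conditions", "must be a non-empty character vector")
  nc <- length(conditions)
  check_prob(mean_recollection, "mean_recollection", len = nc)
  if (!is.numeric(mean_familiarity) || length(mean_familiarity) != nc)
    stop_field("mean_familiarity", sprintf("must have length %d", nc))
  if (length(criteria) != 5L) stop_field("criteria", "must have length 5")
  check_increasing(criteria, "criteria")
  check_nonneg(sd_recollection, "sd_recollection", 1L)
  check_nonneg(sd_familiarity, "sd_familiarity", 1L)
  check_nonneg(sd_criterion_shift, "sd_criterion_shift", 1L)
  check_nonneg(sd_log_increment, "sd_log_increment", 1L)
  check_prob(p_old, "p_old", 1L)
  structure(
    list(conditions = conditions,
         mean_recollection = setNames(mean_recollection, conditions),
         mean_familiarity = setNames(mean_familiarity, conditions),
         criteria = criteria,
         sd_recollection = sd_recollection,
         sd_familiarity = sd_familiarity,
         sd_criterion_shift = sd_criterion_shift,
         sd_log_increment = sd_log_increment,
         n_participants = check_positive_int(n_participants, "n_participants"),
         n_trials_per_condition = check_positive_int(n_trials_per_condition,
                                                     "n_trials_per_condition"),
         p_old = p_old,
         set_size = check_positive_int(set_size, "set_size"),
         seed = as.integer(seed)),
    class = "dpsd_population_spec")
}

#' Fixed-capacity observer specification for change detection
#'
#' A single-probe change-detection observer with capacity `capacity`:
#' the probed item is in memory with probability `min(capacity / N, 1)`;
#' in-memory probes are answered correctly (up to an attentional lapse),
#' otherwise the observer guesses "change" with probability `guess`.
#'
#' `capacity` may be a named vector with one entry per stimulus type to
#' emulate behavioral differences between stimulus classes.
#'
#' @param capacity True capacity in items (scalar, or named per stimulus
#'   type); must be non-negative.
#' @param set_sizes Memory-array set sizes.
#' @param guess Probability of responding "change" when guessing.
#' @param lapse Probability of a random guess regardless of memory.
#' @param n_participants Number of simulated participants.
#' @param n_trials Trials per participant x stimulus type x set size cell.
#' @param seed Default random seed used by [gen_change_detection()].
#'
#' @return An object of class `capacity_observer_spec`.
#' @seealso [gen_change_detection()]
#' @export
capacity_observer_spec <- function(capacity = c(color = 2.6, object = 3.1),
                                   set_sizes = c(1, 3, 5),
                                   guess = 0.5,
                                   lapse = 0.02,
                                   n_participants = 25,
                                   n_trials = 200,
                                   seed = 1L) {
  check_nonneg(capacity, "capacity")
  if (is.null(names(capacity))) {
    if (length(capacity) != 1L)
      stop_field("capacity", "must be scalar or named per stimulus type")
    capacity <- c(stim = unname(capacity))
  }
  check_nonneg(set_sizes, "set_sizes")
  check_prob(guess, "guess", 1L)
  check_prob(lapse, "lapse", 1L)
  structure(
    list(capacity = capacity,
         set_sizes = as.integer(set_sizes),
         guess = guess,
         lapse = lapse,
         n_participants = check_positive_int(n_participants, "n_participants"),
         n_trials = check_positive_int(n_trials, "n_trials"),
         seed = as.integer(seed)),
    class = "capacity_observer_spec")
}

# the eight posterior electrodes entering the CDA, plus ocular channels
cda_eeg_channels <- c("P3", "P4", "P7", "P8", "PO3", "PO4", "PO7", "PO8")
eog_channels <- c("VEOG", "HEOG")
gaze_channels <- c("GAZE_X", "GAZE_Y")

#' Specification for the lateralized ERP epoch simulator
#'
#' Simulates 500-Hz epochs (-200 to 2000 ms around memory-array onset)
#' with a set-size-dependent contralateral negativity over the posterior
#' electrode pairs used for the contralateral delay activity (CDA),
#' 1/f-shaped Gaussian noise, and injectable artifact classes (blink,
#' saccade, drift, muscle, step, flatline), each exceeding its rule-based
#' detection threshold by construction.
#'
#' The contralateral amplitude at set size `N` for stimulus type `s` is
#' `slope_uv * min(N, k_plateau[s]) + delta_uv[s]` microvolts, applied as
#' a sustained deflection from `onset_ms` (with a 100-ms linear rise) to
#' the end of the epoch.  Equal `k_plateau` with a nonzero `delta_uv`
#' difference yields a purely additive stimulus-type offset (the
#' stimulus-driven pattern); distinct `k_plateau` values yield a set-size
#' by stimulus-type interaction (the capacity-expansion pattern).
#'
#' @param n_participants Number of simulated participants.
#' @param stim_types Stimulus-type labels.
#' @param set_sizes Set sizes shown in each hemifield.
#' @param n_trials Trials per participant x stimulus type x set size.
#' @param srate Sampling rate in Hz.
#' @param window Epoch window in ms relative to memory-array onset,
#'   `c(start, end)`; samples are placed on a half-open `[start, end)` grid.
#' @param slope_uv CDA amplitude slope in microvolts per stored item
#'   (negative for the usual contralateral negativity).
#' @param k_plateau Capacity plateau (items) per stimulus type; scalar or
#'   named per type.
#' @param delta_uv Additive stimulus offset in microvolts per type;
#'   scalar or named per type.
#' @param onset_ms Time at which the lateralized deflection reaches full
#'   amplitude (linear rise over the preceding 100 ms).
#' @param noise_sd Noise RMS amplitude in microvolts.
#' @param noise_exponent Spectral exponent of the noise (power ~ 1/f^a);
#'   0 gives white noise.
#' @param artifact_rates Named per-trial injection probabilities for
#'   `blink`, `saccade`, `drift`, `muscle`, `step`, `flatline`.
#' @param gaze If `TRUE`, include eye-tracking channels `GAZE_X`/`GAZE_Y`
#'   (degrees of visual angle).
#' @param channels EEG/EOG channel labels; must contain the eight CDA
#'   electrodes (P3/P4, P7/P8, PO3/PO4, PO7/PO8) and VEOG/HEOG.
#' @param seed Default random seed used by [gen_erp_epochs()].
#'
#' @return An object of class `erp_sim_spec`.
#' @seealso [gen_erp_epochs()], [compute_cda()]
#' @export
erp_sim_spec <- function(n_participants = 18,
                         stim_types = c("color", "object"),
                         set_sizes = c(1, 3, 5),
                         n_trials = 200,
                         srate = 500,
                         window = c(-200, 2000),
                         slope_uv = -0.6,
                         k_plateau = c(color = 3, object = 3),
                         delta_uv = c(color = 0, object = -0.5),
                         onset_ms = 400,
                         noise_sd = 10,
                         noise_exponent = 1,
                         artifact_rates = c(blink = 0, saccade = 0, drift = 0,
                                            muscle = 0, step = 0, flatline = 0),
                         gaze = FALSE,
                         channels = c(cda_eeg_channels, eog_channels),
                         seed = 1L) {
  if (!is.character(stim_types) || length(stim_types) < 1L)
    stop_field("stim_types", "must be a non-empty character vector")
  k_plateau <- expand_by_type(k_plateau, stim_types, "k_plateau")
  delta_uv <- expand_by_type(delta_uv, stim_types, "delta_uv")
  check_nonneg(k_plateau, "k_plateau")
  check_nonneg(noise_sd, "noise_sd", 1L)
  if (length(window) != 2L || window[1] >= window[2])
    stop_field("window", "must be c(start, end) with start < end (ms)")
  known <- c(cda_eeg_channels, eog_channels, gaze_channels)
  bad <- setdiff(channels, known)
  if (length(bad) > 0L)
    stop_field("channels", sprintf("unknown channel(s) %s; valid names are %s",
                                   paste(bad, collapse = ", "),
                                   paste(known, collapse = ", ")))
  missing_cda <- setdiff(c(cda_eeg_channels, eog_channels), channels)
  if (length(missing_cda) > 0L)
    stop_field("channels", sprintf("must include %s",
                                   paste(missing_cda, collapse = ", ")))
  rate_names <- c("blink", "saccade", "drift", "muscle", "step", "flatline")
  rates <- setNames(rep(0, length(rate_names)), rate_names)
  if (length(artifact_rates) > 0L) {
    if (is.null(names(artifact_rates)) ||
        !all(names(artifact_rates) %in% rate_names))
      stop_field("artifact_rates", sprintf("must be named among: %s",
                                           paste(rate_names, collapse = ", ")))
    rates[names(artifact_rates)] <- artifact_rates
  }
  check_prob(rates, "artifact_rates")
  if (isTRUE(gaze)) channels <- union(channels, gaze_channels)
  structure(
    list(n_participants = check_positive_int(n_participants, "n_participants"),
         stim_types = stim_types,
         set_sizes = as.integer(set_sizes),
         n_trials = check_positive_int(n_trials, "n_trials"),
         srate = srate,
         window = window,
         slope_uv = slope_uv,
         k_plateau = k_plateau,
         delta_uv = delta_uv,
         onset_ms = onset_ms,
         noise_sd = noise_sd,
         noise_exponent = noise_exponent,
         artifact_rates = rates,
         gaze = isTRUE(gaze),
         channels = channels,
         seed = as.integer(seed)),
    class = "erp_sim_spec")
}

expand_by_type <- function(x, types, field) {
  if (is.null(names(x))) {
    if (length(x) != 1L)
      stop_field(field, "must be scalar or named per stimulus type")
    return(setNames(rep(unname(x), length(types)), types))
  }
  missing <- setdiff(types, names(x))
  if (length(missing) > 0L)
    stop_field(field, sprintf("missing entries for: %s",
                              paste(missing, collapse = ", ")))
  x[types]
}

#' @export
print.dpsd_population_spec <- function(x, ...) {
  cat("<dpsd_population_spec>\n")
  cat(sprintf("  %d participants x %d conditions x %d trials\n",
              x$n_participants, length(x$conditions), x$n_trials_per_condition))
  cat(sprintf("  R: %s\n", paste(sprintf("%s=%.2f", x$conditions,
                                         x$mean_recollection), collapse = " ")))
  cat(sprintf("  F: %s\n", paste(sprintf("%s=%.2f", x$conditions,
                                         x$mean_familiarity), collapse = " ")))
  cat(sprintf("  criteria: %s\n", paste(format(x$criteria), collapse = " ")))
  invisible(x)
}

#' @export
print.capacity_observer_spec <- function(x, ...) {
  cat("<capacity_observer_spec>\n")
  cat(sprintf("  capacity: %s items; set sizes %s\n",
              paste(sprintf("%s=%.2f", names(x$capacity), x$capacity),
                    collapse = " "),
              paste(x$set_sizes, collapse = "/")))
  cat(sprintf("  %d participants x %d trials per cell\n",
              x$n_participants, x$n_trials))
  invisible(x)
}

#' @export
print.erp_sim_spec <- function(x, ...) {
  cat("<erp_sim_spec>\n")
  cat(sprintf("  %d participants; types %s; set sizes %s; %d trials/cell\n",
              x$n_participants, paste(x$stim_types, collapse = "/"),
              paste(x$set_sizes, collapse = "/"), x$n_trials))
  cat(sprintf("  %g Hz, window [%g, %g) ms, %d channels\n",
              x$srate, x$window[1], x$window[2], length(x$channels)))
  cat(sprintf("  slope %.2f uV/item, plateau %s, offset %s uV, noise %.1f uV\n",
              x$slope_uv,
              paste(sprintf("%s=%g", names(x$k_plateau), x$k_plateau),
                    collapse = " "),
              paste(sprintf("%s=%g", names(x$delta_uv), x$delta_uv),
                    collapse = " "),
              x$noise_sd))
  invisible(x)
}
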