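cda_pairs <- list(c("PO3", "PO4"), c("PO7", "PO8"), c("P3", "P4"),
                  c("P7", "P8"))

default_cda_windows <- function() {
  list(encoding = c(400, 1000), delay = c(1400, 2000),
       combined = c(400, 2000))
}

#' Contralateral delay activity from lateralized epochs
#'
#' Computes, per trial, the mean difference between the posterior
#' electrodes contralateral and ipsilateral to the cued hemifield
#' (pairs PO3/PO4, PO7/PO8, P3/P4, P7/P8), after subtracting the
#' pre-stimulus baseline from every channel.  The difference waveform is
#' averaged over each measurement window (samples in the half-open
#' `[start, end)` interval) and aggregated to participant means per
#' stimulus type and set size, then grand-averaged with the
#' between-participant SEM.
#'
#' @param x An [epoch_set()] whose trial metadata contains
#'   `participant`, `stim_type`, `set_size` and `cue_side`
#'   (`"left"`/`"right"`).
#' @param windows Named list of `c(start, end)` windows in ms; defaults
#'   to encoding 400-1000 ms, delay 1400-2000 ms and the combined
#'   400-2000 ms window.
#' @param baseline `c(start, end)` baseline interval in ms whose mean is
#'   subtracted per channel and epoch, or `NULL` to skip.
#'
#' @return An object of class `cda_result`: a list with
#'   `participant_means` (tibble: participant x stim_type x set_size x
#'   window amplitudes in microvolts), `summary` (grand mean, SEM, n per
#'   cell), `waveforms` (grand-average difference time courses) and
#'   `windows`.
#' @seealso [test_additivity()], [gen_erp_epochs()]
#' @export
compute_cda <- function(x, windows = default_cda_windows(),
                        baseline = c(-200, 0)) {
  stopifnot(inherits(x, "epoch_set"))
  require_columns(x$trials, c("participant", "stim_type", "set_size",
                              "cue_side"), "trial metadata")
  missing <- setdiff(unlist(cda_pairs), x$channels)
  if (length(missing) > 0L)
    abort(sprintf("missing CDA electrode(s): %s",
                  paste(missing, collapse = ", ")))
  if (!all(x$trials$cue_side %in% c("left", "right")))
    abort("cue_side must be 'left' or 'right'")
  times <- epoch_times(x)
  n_trial <- dim(x$data)[1]
  n_samp <- dim(x$data)[3]

  dat <- x$data
  if (!is.null(baseline)) {
    base_idx <- which(times >= baseline[1] & times < baseline[2])
    if (length(base_idx) == 0L) abort("baseline interval contains no samples")
    base_mean <- apply(dat[, , base_idx, drop = FALSE], c(1, 2), mean)
    dat <- dat - array(base_mean, dim = dim(dat))
  }

  left_ch <- match(vapply(cda_pairs, `[`, "", 1L), x$channels)
  right_ch <- match(vapply(cda_pairs, `[`, "", 2L), x$channels)
  cue_left <- x$trials$cue_side == "left"
  # contra - ipsi averaged over the four pairs, trial x sample
  diff_wave <- matrix(0, n_trial, n_samp)
  for (p in seq_along(cda_pairs)) {
    l <- matrix(dat[, left_ch[p], ], nrow = n_trial)
    r <- matrix(dat[, right_ch[p], ], nrow = n_trial)
    d <- r - l                       # contra - ipsi for left-cue trials
    d[!cue_left, ] <- -d[!cue_left, ]
    diff_wave <- diff_wave + d
  }
  diff_wave <- diff_wave / length(cda_pairs)

  win_means <- imap(windows, function(w, nm) {
    idx <- which(times >= w[1] & times < w[2])
    if (length(idx) == 0L)
      abort(sprintf("window '%s' contains no samples", nm))
    tibble(window = nm, trial = seq_len(n_trial),
           amplitude = rowMeans(diff_wave[, idx, drop = FALSE]))
  }) |> bind_rows()

  meta <- x$trials |>
    mutate(trial = seq_len(n_trial)) |>
    select("trial", "participant", "stim_type", "set_size")
  participant_means <- win_means |>
    left_join(meta, by = "trial") |>
    group_by(.data$participant, .data$stim_type, .data$set_size,
             .data$window) |>
    summarise(amplitude = mean(.data$amplitude), n_trials = n(),
              .groups = "drop")
  summary <- participant_means |>
    group_by(.data$stim_type, .data$set_size, .data$window) |>
    summarise(mean = mean(.data$amplitude),
              sem = sd(.data$amplitude) / sqrt(n()),
              n = n(), .groups = "drop")
  waveforms <- tibble(trial = seq_len(n_trial)) |>
    left_join(meta, by = "trial") |>
    bind_cols(as_tibble(diff_wave,
                        .name_repair = ~ paste0("smp", seq_len(n_samp)))) |>
    group_by(.data$stim_type, .data$set_size) |>
    summarise(across(starts_with("smp"), mean), .groups = "drop") |>
    pivot_longer(starts_with("smp"), names_to = "sample",
                 values_to = "amplitude") |>
    mutate(time = times[as.integer(sub("^smp", "", .data$sample))]) |>
    select("stim_type", "set_size", "time", "amplitude")

  structure(list(participant_means = participant_means, summary = summary,
                 waveforms = waveforms, windows = windows),
            class = "cda_result")
}

#' @export
print.cda_result <- function(x, ...) {
  cat("<cda_result> grand-average contra - ipsi amplitude (uV)\n")
  wide <- x$summary |>
    mutate(cell = sprintf("%s (n=%d)", .data$window, .data$n)) |>
    select("stim_type", "set_size", "cell", "mean") |>
    pivot_wider(names_from = "cell", values_from = "mean")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname compute_cda
#' @param x,object A `cda_result`.
#' @param ... Unused.
#' @method tidy cda_result
#' @export
tidy.cda_result <- function(x, ...) x$participant_means

#' @rdname compute_cda
#' @method glance cda_result
#' @export
glance.cda_result <- function(x, ...) {
  tibble(n_participants = length(unique(x$participant_means$participant)),
         n_cells = nrow(x$summary), n_windows = length(x$windows))
}

#' Set-size by stimulus-type additivity test on CDA amplitudes
#'
#' Distinguishes the two competing accounts of a stimulus-type
#' difference in CDA amplitude: genuine extra storage predicts a
#' set-size by stimulus-type interaction (the amplitude gap grows with
#' load), whereas a stimulus-driven offset predicts an additive pattern
#' (main effect of type, no interaction).  A two-way repeated-measures
#' ANOVA is run on the per-participant window amplitudes; the verdict is
#' `"additive"` when the type main effect is significant and the
#' interaction is not, `"interactive"` when the interaction is
#' significant, and `"indeterminate"` otherwise.
#'
#' @param x A [compute_cda()] result, or a tibble of per-participant
#'   cell means with columns `participant`, `stim_type`, `set_size` and
#'   `amplitude`.
#' @param window Which measurement window to test (ignored for a plain
#'   tibble input).
#' @param alpha Significance level.
#'
#' @return An object of class `additivity_test`: a list with `anova`
#'   (the [rm_anova()] table), `verdict`, `alpha` and `window`.
#' @export
test_additivity <- function(x, window = "combined", alpha = 0.05) {
  cells <- if (inherits(x, "cda_result")) {
    if (!window %in% unique(x$participant_means$window))
      abort(sprintf("window '%s' not present in the CDA result", window))
    x$participant_means |> filter(.data$window == !!window)
  } else {
    window <- NA_character_
    as_tibble(x)
  }
  require_columns(cells, c("participant", "stim_type", "set_size",
                           "amplitude"), "cell means")
  if (length(unique(cells$stim_type)) < 2L ||
      length(unique(cells$set_size)) < 2L)
    abort("need at least 2 stimulus types and 2 set sizes",
          class = "wmcda_design_error")
  tab <- rm_anova(cells, dv = "amplitude",
                  within = c("stim_type", "set_size"))
  p_type <- tab$p.value[tab$effect == "stim_type"]
  p_int <- tab$p.value[tab$effect == "stim_type:set_size"]
  verdict <- if (p_int < alpha) "interactive"
             else if (p_type < alpha) "additive"
             else "indeterminate"
  structure(list(anova = tab, verdict = verdict, alpha = alpha,
                 window = window),
            class = "additivity_test")
}

#' @export
print.additivity_test <- function(x, ...) {
  cat(sprintf("<additivity_test> verdict: %s (alpha = %.2f%s)\n",
              x$verdict, x$alpha,
              if (is.na(x$window)) "" else paste0(", window ", x$window)))
  print(as.data.frame(x$anova), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname test_additivity
#' @param x,object An `additivity_test`.
#' @param ... Unused.
#' @method tidy additivity_test
#' @export
tidy.additivity_test <- function(x, ...) x$anova

#' @rdname test_additivity
#' @method glance additivity_test
#' @export
glance.additivity_test <- function(x, ...) {
  tibble(verdict = x$verdict, alpha = x$alpha, window = x$window,
         p_interaction = x$anova$p.value[x$anova$effect == "stim_type:set_size"],
         p_type = x$anova$p.value[x$anova$effect == "stim_type"])
}

#' Simulate per-participant CDA window means directly
#'
#' Summary-level counterpart of [gen_erp_epochs()]: draws per-
#' participant mean CDA amplitudes for each stimulus type x set size
#' cell from the same amplitude function
#' `slope_uv * min(N, k_plateau) + delta_uv`, plus a participant random
#' intercept and residual cell noise.  Useful for calibration studies
#' (e.g. type-I error of the additivity test over hundreds of simulated
#' experiments) where generating full epoched EEG would be wasteful.
#'
#' @param n_participants Number of participants.
#' @param stim_types,set_sizes Design factors.
#' @param slope_uv,k_plateau,delta_uv Amplitude function, as in
#'   [erp_sim_spec()].
#' @param participant_sd SD of the participant random intercept
#'   (microvolts).
#' @param resid_sd SD of the residual cell noise (microvolts).
#' @param seed Integer seed.
#'
#' @return A tibble with `participant`, `stim_type`, `set_size`,
#'   `amplitude` — ready for [test_additivity()].
#' @export
sim_cda_cell_means <- function(n_participants = 18,
                               stim_types = c("color", "object"),
                               set_sizes = c(1, 3, 5),
                               slope_uv = -0.6,
                               k_plateau = c(color = 3, object = 3),
                               delta_uv = c(color = 0, object = -0.5),
                               participant_sd = 0.8,
                               resid_sd = 0.5,
                               seed = 1L) {
  k_plateau <- expand_by_type(k_plateau, stim_types, "k_plateau")
  delta_uv <- expand_by_type(delta_uv, stim_types, "delta_uv")
  withr::with_seed(as.integer(seed), {
    ids <- participant_labels(n_participants)
    intercept <- setNames(rnorm(n_participants, 0, participant_sd), ids)
    expand_grid(participant = ids, stim_type = stim_types,
                set_size = set_sizes) |>
      mutate(amplitude = slope_uv * pmin(.data$set_size,
                                         k_plateau[.data$stim_type]) +
               delta_uv[.data$stim_type] +
               intercept[.data$participant] +
               rnorm(n(), 0, resid_sd))
  })
}
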