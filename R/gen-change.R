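#' Simulate single-probe change-detection trials from a fixed-capacity
#' observer
#'
#' Each trial probes one item of an `N`-item array.  The probed item is
#' held in memory with probability `min(capacity / N, 1)`; a remembered
#' probe is answered correctly, otherwise the observer responds "change"
#' with the guessing probability.  An optional lapse rate replaces the
#' memory-based response with a guess.  Under this observer, Cowan's K
#' computed from hit and false-alarm rates recovers
#' `min(capacity, N) * (1 - lapse)` in expectation.
#'
#' @param spec A [capacity_observer_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#'
#' @return A tibble with one row per trial: `participant`, `stim_type`,
#'   `set_size`, `trial`, `change` (logical ground truth) and
#'   `said_change` (logical response).
#'
#' @examples
#' spec <- capacity_observer_spec(capacity = 3, n_participants = 2,
#'                                n_trials = 40)
#' trials <- gen_change_detection(spec, seed = 2)
#' compute_rates(trials)
#' @export
gen_change_detection <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "capacity_observer_spec"))
  withr::with_seed(as.integer(seed), {
    grid <- expand_grid(participant = participant_labels(spec$n_participants),
                        stim_type = names(spec$capacity),
                        set_size = spec$set_sizes)
    out <- grid |>
      mutate(data = pmap(list(.data$stim_type, .data$set_size),
                         function(type, n) {
                           sim_change_cell(spec$capacity[[type]], n,
                                           spec$guess, spec$lapse,
                                           spec$n_trials)
                         })) |>
      tidyr::unnest("data")
    out |>
      mutate(participant = factor(.data$participant),
             stim_type = factor(.data$stim_type, levels = names(spec$capacity)))
  })
}

sim_change_cell <- function(capacity, set_size, guess, lapse, n_trials) {
  change <- runif(n_trials) < 0.5
  in_memory <- runif(n_trials) < min(capacity / set_size, 1)
  guessing <- !in_memory | (runif(n_trials) < lapse)
  said <- ifelse(guessing, runif(n_trials) < guess, change)
  tibble(trial = seq_len(n_trials), change = change,
         said_change = as.logical(said))
}
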