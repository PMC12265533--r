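#' Simulate confidence-rating recognition trials from the DPSD model
#'
#' Draws trial-level 6-bin confidence responses from the dual-process
#' signal-detection generative model.  For an old probe, with
#' probability R (the participant's recollection parameter) the response
#' is the highest-confidence "surely-old" bin; otherwise a familiarity
#' value is drawn from a unit-variance normal centred at the
#' participant's familiarity strength and binned by their ordered
#' criteria.  New probes draw familiarity from the standard normal.
#' Recollection never occurs for new probes.
#'
#' Participant-level parameters are sampled around the population means
#' on transformed scales (probit for recollection, identity for
#' familiarity, a common additive shift plus log-increment jitter for
#' the criteria) so that every draw respects the model's constraints.
#'
#' @param spec A [dpsd_population_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#'   Identical spec and seed give identical output.
#'
#' @return A tibble with one row per trial: `participant`, `condition`,
#'   `trial`, `set_size`, `probe_status` (`"old"`/`"new"`) and `bin`
#'   (1 = surely-new ... 6 = surely-old).
#'
#' @examples
#' spec <- dpsd_population_spec(n_participants = 4,
#'                              n_trials_per_condition = 24)
#' trials <- gen_recognition_trials(spec, seed = 7)
#' dplyr::count(trials, condition, probe_status)
#' @export
gen_recognition_trials <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dpsd_population_spec"))
  withr::with_seed(as.integer(seed), {
    params <- draw_participant_params(spec)
    n_old <- round(spec$n_trials_per_condition * spec$p_old)
    n_new <- spec$n_trials_per_condition - n_old
    out <- params |>
      mutate(trials = pmap(list(.data$recollection, .data$familiarity,
                                .data$criteria),
                           function(r, f, crit) {
                             sim_condition_trials(r, f, crit, n_old, n_new)
                           })) |>
      select("participant", "condition", "trials") |>
      tidyr::unnest("trials")
    out |>
      mutate(set_size = spec$set_size, .after = "trial") |>
      mutate(participant = factor(.data$participant),
             condition = factor(.data$condition, levels = spec$conditions))
  })
}

# participant-level DPSD parameters on the natural scale
draw_participant_params <- function(spec) {
  ids <- participant_labels(spec$n_participants)
  log_incr <- log(diff(spec$criteria))
  per_part <- tibble(
    participant = ids,
    z_r = rnorm(spec$n_participants, 0, spec$sd_recollection),
    z_f = rnorm(spec$n_participants, 0, spec$sd_familiarity),
    shift = rnorm(spec$n_participants, 0, spec$sd_criterion_shift),
    criteria = map(.data$shift, function(s) {
      incr <- exp(log_incr + rnorm(4, 0, spec$sd_log_increment))
      spec$criteria[1] + s + c(0, cumsum(incr))
    })
  )
  expand_grid(participant = ids, condition = spec$conditions) |>
    left_join(per_part, by = "participant") |>
    mutate(
      recollection = pnorm(qnorm(spec$mean_recollection[.data$condition]) +
                             .data$z_r),
      familiarity = spec$mean_familiarity[.data$condition] + .data$z_f) |>
    select("participant", "condition", "recollection", "familiarity",
           "criteria")
}

sim_condition_trials <- function(r, f, criteria, n_old, n_new) {
  recollected <- runif(n_old) < r
  x_old <- rnorm(n_old, mean = f, sd = 1)
  bin_old <- findInterval(x_old, criteria) + 1L
  bin_old[recollected] <- 6L
  x_new <- rnorm(n_new, mean = 0, sd = 1)
  bin_new <- findInterval(x_new, criteria) + 1L
  tibble(trial = seq_len(n_old + n_new),
         probe_status = rep(c("old", "new"), c(n_old, n_new)),
         bin = c(bin_old, bin_new))
}
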