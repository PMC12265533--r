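#' Configuration for the end-to-end experiment runners
#'
#' [run_exp1()] reproduces the recognition-experiment analysis chain:
#' hit/false-alarm rates and Cowan's K per condition with a one-way
#' repeated-measures ANOVA and Bonferroni-corrected pairwise tests,
#' empirical ROCs, and the hierarchical Bayesian DPSD fit.
#' [run_exp2()] reproduces the lateralized change-detection analysis:
#' Cowan's K by stimulus type and set size with the two-way ANOVA,
#' artifact rejection and participant exclusion, windowed CDA
#' amplitudes, and the set-size by stimulus-type additivity verdict.
#'
#' Exactly one of a synthetic spec or a real trial table (tibble or CSV
#' path) must be supplied for each data source; the defaults run fully
#' synthetic analyses at the study's design sizes.
#'
#' @param spec A [dpsd_population_spec()] for the recognition data, or
#'   `NULL` when `trials` is given.
#' @param trials Recognition trial tibble or CSV path, or `NULL`.
#' @param preset Sampler preset for [fit_dpsd()].
#' @param fit_args Named list of extra arguments passed on to
#'   [fit_dpsd()] (e.g. a smaller chain budget).
#' @param alpha Significance level for the ANOVA and pairwise tests.
#' @param seed Integer seed controlling data generation (when synthetic)
#'   and the sampler chains.
#' @return A configuration list.
#' @export
exp1_config <- function(spec = dpsd_population_spec(), trials = NULL,
                        preset = "test", fit_args = list(),
                        alpha = 0.05, seed = 1L) {
  if (is.null(spec) == is.null(trials))
    abort("provide exactly one of `spec` (synthetic) or `trials` (real data)",
          class = "wmcda_config_error")
  list(spec = spec, trials = trials, preset = preset, fit_args = fit_args,
       alpha = alpha, seed = as.integer(seed))
}

#' @rdname exp1_config
#' @param behavior_spec A [capacity_observer_spec()] for the behavioral
#'   change-detection data, or `NULL` when `behavior_trials` is given.
#' @param behavior_trials Change-detection trial tibble or CSV path, or
#'   `NULL`.
#' @param erp_spec An [erp_sim_spec()] for the epoched EEG, or `NULL`
#'   when `epochs` is given.
#' @param epochs An [epoch_set()] or epoch-directory path, or `NULL`.
#' @param max_rejection_rate Participant-exclusion threshold on the
#'   trial rejection rate.
#' @export
exp2_config <- function(behavior_spec = capacity_observer_spec(),
                        behavior_trials = NULL,
                        erp_spec = erp_sim_spec(),
                        epochs = NULL,
                        max_rejection_rate = 0.30,
                        alpha = 0.05, seed = 1L) {
  if (is.null(behavior_spec) == is.null(behavior_trials))
    abort("provide exactly one of `behavior_spec` or `behavior_trials`",
          class = "wmcda_config_error")
  if (is.null(erp_spec) == is.null(epochs))
    abort("provide exactly one of `erp_spec` or `epochs`",
          class = "wmcda_config_error")
  list(behavior_spec = behavior_spec, behavior_trials = behavior_trials,
       erp_spec = erp_spec, epochs = epochs,
       max_rejection_rate = max_rejection_rate, alpha = alpha,
       seed = as.integer(seed))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "wmcda_stage_error", parent = e)
  })
}

#' Run the recognition-experiment analysis end to end
#'
#' @param config An [exp1_config()].
#' @return An object of class `exp1_report`: a list with `trials`,
#'   `rates` (per-participant hit/FA/K), `rate_anova` (one-way RM-ANOVA
#'   per measure), `pairwise_k`, `roc`, and `fit` (the [fit_dpsd()]
#'   result).  Deterministic for a fixed config and seed.
#' @export
run_exp1 <- function(config = exp1_config()) {
  trials <- run_stage("data", {
    if (!is.null(config$spec)) {
      gen_recognition_trials(config$spec, seed = config$seed)
    } else if (is.character(config$trials)) {
      read_trials(config$trials, "recognition")
    } else {
      check_trial_schema(config$trials, "recognition")
    }
  })
  rates <- run_stage("rates", compute_rates(trials))
  rate_anova <- run_stage("anova", {
    map(c(k = "k", hit_rate = "hit_rate", fa_rate = "fa_rate"),
        function(dv) rm_anova(rates, dv = dv, within = "condition"))
  })
  pairwise_k <- run_stage("pairwise",
                          pairwise_tests(rates, dv = "k",
                                         within = "condition"))
  roc <- run_stage("roc", build_roc(trials))
  fit <- run_stage("dpsd", do.call(fit_dpsd, c(
    list(trials, preset = config$preset, seed = config$seed + 1L),
    config$fit_args)))
  structure(list(trials = trials, rates = rates, rate_anova = rate_anova,
                 pairwise_k = pairwise_k, roc = roc, fit = fit,
                 alpha = config$alpha),
            class = "exp1_report")
}

#' @export
print.exp1_report <- function(x, ...) {
  cat("<exp1_report>\n\nCowan's K by condition:\n")
  ks <- x$rates |>
    group_by(.data$condition) |>
    summarise(mean_k = mean(.data$k), sd_k = sd(.data$k),
              hit = mean(.data$hit_rate), fa = mean(.data$fa_rate))
  print(as.data.frame(ks), digits = 3, row.names = FALSE)
  cat("\nOne-way RM-ANOVA on K:\n")
  print(as.data.frame(x$rate_anova$k), digits = 3, row.names = FALSE)
  cat("\nDPSD population estimates:\n")
  print(x$fit)
  invisible(x)
}

#' Run the lateralized change-detection analysis end to end
#'
#' @param config An [exp2_config()].
#' @return An object of class `exp2_report`: a list with
#'   `behavior_trials`, `rates` (K by stimulus type and set size),
#'   `k_anova` (two-way RM-ANOVA), `rejection` (the
#'   [reject_and_exclude()] report), `cda` (the [compute_cda()] result)
#'   and `additivity` (the [test_additivity()] verdict).
#' @export
run_exp2 <- function(config = exp2_config()) {
  behavior <- run_stage("behavior", {
    if (!is.null(config$behavior_spec)) {
      gen_change_detection(config$behavior_spec, seed = config$seed)
    } else if (is.character(config$behavior_trials)) {
      read_trials(config$behavior_trials, "change")
    } else {
      check_trial_schema(config$behavior_trials, "change")
    }
  })
  rates <- run_stage("rates", compute_rates(behavior))
  k_anova <- run_stage("anova",
                       rm_anova(rates, dv = "k",
                                within = c("stim_type", "set_size")))
  epochs <- run_stage("epochs", {
    if (!is.null(config$erp_spec)) {
      gen_erp_epochs(config$erp_spec, seed = config$seed + 1L)
    } else if (is.character(config$epochs)) {
      read_epoch_set(config$epochs)
    } else {
      config$epochs
    }
  })
  rejection <- run_stage("rejection",
                         reject_and_exclude(epochs,
                                            config$max_rejection_rate))
  cda <- run_stage("cda", compute_cda(rejection$epochs))
  additivity <- run_stage("additivity",
                          test_additivity(cda, alpha = config$alpha))
  structure(list(behavior_trials = behavior, rates = rates,
                 k_anova = k_anova, rejection = rejection, cda = cda,
                 additivity = additivity),
            class = "exp2_report")
}

#' @export
print.exp2_report <- function(x, ...) {
  cat("<exp2_report>\n\nCowan's K by stimulus type and set size:\n")
  ks <- x$rates |>
    group_by(.data$stim_type, .data$set_size) |>
    summarise(mean_k = mean(.data$k), sd_k = sd(.data$k), .groups = "drop")
  print(as.data.frame(ks), digits = 3, row.names = FALSE)
  cat("\n")
  print(x$rejection)
  cat("\n")
  print(x$cda)
  cat("\n")
  print(x$additivity)
  invisible(x)
}
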