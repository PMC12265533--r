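dpsd_model_template <- "
model {
  for (c in 1:C) {
    muR[c] ~ dnorm(0, %(tau_fixed));
    muF[c] ~ dnorm(0, %(tau_fixed));
  }
  sdR ~ dnorm(0, %(tau_sd)) T(0,);
  sdF ~ dnorm(0, %(tau_sd)) T(0,);
  mu_c1 ~ dnorm(0, %(tau_fixed));
  for (k in 1:4) { mu_lg[k] ~ dnorm(0, %(tau_fixed)); }
  sd_c1 ~ dnorm(0, %(tau_sd)) T(0,);
  sd_lg ~ dnorm(0, %(tau_sd)) T(0,);
  for (j in 1:J) {
    zR[j] ~ dnorm(0, 1);
    zF[j] ~ dnorm(0, 1);
    zc1[j] ~ dnorm(0, 1);
    for (k in 1:4) { zlg[j, k] ~ dnorm(0, 1); }
    crit[j, 1] <- mu_c1 + sd_c1 * zc1[j];
    for (k in 2:5) {
      crit[j, k] <- crit[j, k - 1] + exp(mu_lg[k - 1] + sd_lg * zlg[j, k - 1]);
    }
    for (c in 1:C) {
      R[j, c] <- phi(muR[c] + sdR * zR[j]);
      FF[j, c] <- muF[c] + sdF * zF[j];
      for (k in 1:5) {
        hr[j, c, k] <- R[j, c] + (1 - R[j, c]) * phi(FF[j, c] - crit[j, k]);
        fr[j, c, k] <- phi(-crit[j, k]);
      }
      pold[j, c, 1] <- 1 - hr[j, c, 1];
      pnew[j, c, 1] <- 1 - fr[j, c, 1];
      for (k in 2:5) {
        pold[j, c, k] <- hr[j, c, k - 1] - hr[j, c, k];
        pnew[j, c, k] <- fr[j, c, k - 1] - fr[j, c, k];
      }
      pold[j, c, 6] <- hr[j, c, 5];
      pnew[j, c, 6] <- fr[j, c, 5];
      yold[j, c, 1:6] ~ dmulti(pold[j, c, 1:6], nold[j, c]);
      ynew[j, c, 1:6] ~ dmulti(pnew[j, c, 1:6], nnew[j, c]);
    }
  }
}"

#' Prior settings for the hierarchical DPSD model
#'
#' Weakly informative defaults: Normal(0, `sd_fixed`) on all fixed
#' effects (probit-recollection and familiarity condition means, first
#' criterion and log criterion increments) and half-Normal(`sd_random`)
#' on the between-participant standard deviations.
#'
#' @param sd_fixed SD of the normal prior on fixed effects.
#' @param sd_random Scale of the half-normal prior on random-effect SDs.
#' @return A named list.
#' @export
dpsd_priors <- function(sd_fixed = 1.5, sd_random = 1) {
  check_nonneg(sd_fixed, "sd_fixed", 1L)
  check_nonneg(sd_random, "sd_random", 1L)
  list(sd_fixed = sd_fixed, sd_random = sd_random)
}

#' Fit the hierarchical Bayesian DPSD model
#'
#' Estimates population-level recollection and familiarity per condition
#' (plus shared ordered criteria) from binned confidence-rating
#' recognition trials, with participant random effects on all
#' parameters.  Recollection is modeled on the probit scale,
#' familiarity on the identity scale, and the five ordered criteria as a
#' first criterion plus log-increments; the linear predictor of each
#' participant-condition parameter is the sum of the condition fixed
#' effect and the participant random effect.  Sampling uses MCMC through
#' JAGS; draws are reproducible for a fixed seed, chain count and JAGS
#' version.
#'
#' The `"full"` preset draws 12,000 samples per chain after 12,000
#' warm-up iterations; the `"test"` preset (default) is a reduced budget
#' of 3,000 samples after 2,000 warm-up iterations per chain, suitable
#' for test suites and quick recovery checks.
#'
#' @param trials Recognition trial tibble (`participant`, `condition`,
#'   `probe_status`, `bin`) with at least 2 participants and 2
#'   conditions.
#' @param preset `"test"` or `"full"` sampler budget; individual
#'   settings below override the preset.
#' @param chains Number of MCMC chains.
#' @param n_adapt,n_warmup,n_iter Adaptation, warm-up (burn-in) and
#'   retained iterations per chain.
#' @param seed Integer seed for the chain RNGs.
#' @param priors A [dpsd_priors()] list.
#' @param monitor_participants Keep participant-level draws (needed by
#'   [roc_overlay()]).
#' @param population How population summaries are formed: `"fixed"`
#'   (default) transforms the fixed-effect chains, `"participant_mean"`
#'   averages participant-level draws per iteration.
#' @param rhat_limit Population-level split-chain R-hat above which the
#'   fit is flagged as non-converged (a warning; results are still
#'   returned).
#' @param quiet Suppress JAGS progress output.
#'
#' @return An object of class `dpsd_fit` with elements `summary` (tibble
#'   of population-level posterior means, 95% HDIs, R-hat and effective
#'   sample sizes), `samples` (a `coda::mcmc.list`), `converged`,
#'   `settings`, `conditions` and `participants`.  Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @seealso [gen_recognition_trials()], [summarize_posterior()]
#' @export
fit_dpsd <- function(trials,
                     preset = c("test", "full"),
                     chains = 4,
                     n_adapt = NULL, n_warmup = NULL, n_iter = NULL,
                     seed = 1L,
                     priors = dpsd_priors(),
                     monitor_participants = TRUE,
                     population = c("fixed", "participant_mean"),
                     rhat_limit = 1.1,
                     quiet = TRUE) {
  preset <- match.arg(preset)
  population <- match.arg(population)
  budget <- switch(preset,
                   test = list(adapt = 1000, warmup = 2000, iter = 3000),
                   full = list(adapt = 1000, warmup = 12000, iter = 12000))
  n_adapt <- n_adapt %||% budget$adapt
  n_warmup <- n_warmup %||% budget$warmup
  n_iter <- n_iter %||% budget$iter

  counts <- count_responses(trials)
  participants <- levels(factor(counts$participant))
  conditions <- levels(factor(counts$condition))
  J <- length(participants)
  C <- length(conditions)
  if (J < 2L) abort("need at least 2 participants")
  if (C < 2L) abort("need at least 2 conditions")
  yold <- array(0L, c(J, C, 6))
  ynew <- array(0L, c(J, C, 6))
  idx_j <- match(counts$participant, participants)
  idx_c <- match(counts$condition, conditions)
  for (i in seq_len(nrow(counts))) {
    if (counts$probe_status[i] == "old")
      yold[idx_j[i], idx_c[i], counts$bin[i]] <- counts$n[i]
    else
      ynew[idx_j[i], idx_c[i], counts$bin[i]] <- counts$n[i]
  }

  model_string <- dpsd_model_template
  model_string <- gsub("%(tau_fixed)", format(1 / priors$sd_fixed^2),
                       model_string, fixed = TRUE)
  model_string <- gsub("%(tau_sd)", format(1 / priors$sd_random^2),
                       model_string, fixed = TRUE)
  data <- list(J = J, C = C, yold = yold, ynew = ynew,
               nold = apply(yold, 1:2, sum), nnew = apply(ynew, 1:2, sum))
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  monitors <- c("muR", "muF", "sdR", "sdF", "mu_c1", "mu_lg", "sd_c1", "sd_lg")
  if (monitor_participants) monitors <- c(monitors, "R", "FF", "crit")

  pb <- if (quiet) "none" else "text"
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = quiet)
  stats::update(jm, n_warmup, progress.bar = pb)
  samples <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                                 progress.bar = pb)

  smry <- dpsd_population_summary(samples, conditions, J, population,
                                  monitor_participants)
  converged <- all(smry$rhat <= rhat_limit, na.rm = TRUE)
  if (!converged)
    warning(sprintf("non-convergence: population-level R-hat up to %.3f exceeds %.2f",
                    max(smry$rhat, na.rm = TRUE), rhat_limit), call. = FALSE)
  structure(list(summary = smry, samples = samples, converged = converged,
                 conditions = conditions, participants = participants,
                 settings = list(preset = preset, chains = chains,
                                 n_adapt = n_adapt, n_warmup = n_warmup,
                                 n_iter = n_iter, seed = as.integer(seed),
                                 priors = priors, population = population),
                 counts = counts),
            class = "dpsd_fit")
}

# iterations x chains matrix for one monitored scalar
draws_matrix <- function(samples, name) {
  vapply(samples, function(ch) as.vector(ch[, name]),
         numeric(nrow(samples[[1]])))
}

dpsd_population_summary <- function(samples, conditions, J, population,
                                    has_participants) {
  C <- length(conditions)
  rows <- list()
  pop_draws <- function(prefix, c) {
    if (population == "participant_mean" && has_participants) {
      mats <- lapply(seq_len(J), function(j) {
        draws_matrix(samples, sprintf("%s[%d,%d]", prefix, j, c))
      })
      Reduce(`+`, mats) / J
    } else if (prefix == "R") {
      pnorm(draws_matrix(samples, sprintf("muR[%d]", c)))
    } else {
      draws_matrix(samples, sprintf("muF[%d]", c))
    }
  }
  for (c in seq_len(C)) {
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(parameter = "recollection", condition = conditions[c]),
      summarize_posterior(pop_draws("R", c)))
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(parameter = "familiarity", condition = conditions[c]),
      summarize_posterior(pop_draws("FF", c)))
  }
  # population criteria from the fixed-effect chains
  c1 <- draws_matrix(samples, "mu_c1")
  crit <- c1
  for (k in 1:5) {
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(parameter = sprintf("criterion_%d", k), condition = NA_character_),
      summarize_posterior(crit))
    if (k < 5)
      crit <- crit + exp(draws_matrix(samples, sprintf("mu_lg[%d]", k)))
  }
  for (nm in c("sdR", "sdF", "sd_c1", "sd_lg")) {
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(parameter = nm, condition = NA_character_),
      summarize_posterior(draws_matrix(samples, nm)))
  }
  bind_rows(rows)
}

#' @export
print.dpsd_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<dpsd_fit> %d participants x %d conditions; %d chains x %d draws (%s preset)\n",
              length(x$participants), length(x$conditions), s$chains,
              s$n_iter, s$preset))
  cat(sprintf("  converged: %s (max population R-hat %.3f)\n",
              x$converged, max(x$summary$rhat, na.rm = TRUE)))
  main <- x$summary |> filter(.data$parameter %in% c("recollection",
                                                     "familiarity"))
  print(as.data.frame(main), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_dpsd
#' @param x,object A `dpsd_fit`.
#' @param ... Unused.
#' @method tidy dpsd_fit
#' @export
tidy.dpsd_fit <- function(x, ...) x$summary

#' @rdname fit_dpsd
#' @method glance dpsd_fit
#' @export
glance.dpsd_fit <- function(x, ...) {
  tibble(n_participants = length(x$participants),
         n_conditions = length(x$conditions),
         chains = x$settings$chains,
         n_warmup = x$settings$n_warmup,
         n_draws = x$settings$n_iter * x$settings$chains,
         max_rhat = max(x$summary$rhat, na.rm = TRUE),
         converged = x$converged)
}

#' Posterior-mean participant-level DPSD parameters
#'
#' @param fit A [fit_dpsd()] result fitted with
#'   `monitor_participants = TRUE`.
#' @return A tibble with `participant`, `condition`, `recollection`,
#'   `familiarity` and `criteria` (list-column of length-5 vectors).
#' @export
participant_params <- function(fit) {
  stopifnot(inherits(fit, "dpsd_fit"))
  if (!any(grepl("^R\\[", coda::varnames(fit$samples))))
    abort("fit was run with monitor_participants = FALSE")
  J <- length(fit$participants)
  C <- length(fit$conditions)
  post_mean <- function(name) mean(draws_matrix(fit$samples, name))
  expand_grid(j = seq_len(J), c = seq_len(C)) |>
    mutate(participant = fit$participants[.data$j],
           condition = fit$conditions[.data$c],
           recollection = map_dbl(seq_len(n()), function(i)
             post_mean(sprintf("R[%d,%d]", j[i], c[i]))),
           familiarity = map_dbl(seq_len(n()), function(i)
             post_mean(sprintf("FF[%d,%d]", j[i], c[i]))),
           criteria = map(.data$j, function(jj)
             vapply(1:5, function(k)
               post_mean(sprintf("crit[%d,%d]", jj, k)), 1.0))) |>
    select("participant", "condition", "recollection", "familiarity",
           "criteria")
}
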