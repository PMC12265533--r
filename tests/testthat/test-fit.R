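# small-budget sampler runs: structure, determinism, and downstream
# accessors; recovery quality at full design size lives in the
# acceptance suite

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- dpsd_population_spec(n_participants = 6,
                                   n_trials_per_condition = 60)
      trials <- gen_recognition_trials(spec, seed = 51)
      cache <<- list(
        trials = trials,
        fit = suppressWarnings(
          fit_dpsd(trials, chains = 2, n_adapt = 300, n_warmup = 400,
                   n_iter = 400, seed = 51)))
    }
    cache
  }
})

test_that("the hierarchical fit returns a complete population summary", {
  fit <- small_fit()$fit
  s <- fit$summary
  expect_equal(sum(s$parameter == "recollection"), 3)
  expect_equal(sum(s$parameter == "familiarity"), 3)
  expect_equal(sum(grepl("^criterion_", s$parameter)), 5)
  expect_true(all(s$hdi_lower <= s$mean & s$mean <= s$hdi_upper))
  r <- s[s$parameter == "recollection", ]
  expect_true(all(r$mean > 0 & r$mean < 1))
  crit <- s$mean[grepl("^criterion_", s$parameter)]
  expect_true(all(diff(crit) > 0))
})

test_that("fits are reproducible under a fixed seed", {
  d <- small_fit()
  refit <- suppressWarnings(
    fit_dpsd(d$trials, chains = 2, n_adapt = 300, n_warmup = 400,
             n_iter = 400, seed = 51))
  expect_equal(refit$summary$mean, d$fit$summary$mean, tolerance = 1e-12)
  other <- suppressWarnings(
    fit_dpsd(d$trials, chains = 2, n_adapt = 300, n_warmup = 400,
             n_iter = 400, seed = 52))
  expect_false(isTRUE(all.equal(other$summary$mean, d$fit$summary$mean,
                                tolerance = 1e-12)))
})

test_that("tidiers and participant-level accessors are consistent", {
  d <- small_fit()
  expect_identical(tidy(d$fit), d$fit$summary)
  g <- glance(d$fit)
  expect_equal(g$n_participants, 6)
  expect_equal(g$n_draws, 800)
  pp <- participant_params(d$fit)
  expect_equal(nrow(pp), 6 * 3)
  expect_true(all(pp$recollection > 0 & pp$recollection < 1))
  expect_true(all(vapply(pp$criteria, function(cr) all(diff(cr) > 0), TRUE)))
})

test_that("the ROC overlay pairs observations with predictions per participant", {
  d <- small_fit()
  ov <- roc_overlay(d$fit, d$trials, n_grid = 21)
  expect_setequal(unique(ov$series), c("observed", "predicted"))
  obs <- dplyr::filter(ov, series == "observed")
  expect_equal(nrow(obs), 6 * 3 * 5)
  stranger <- dplyr::mutate(d$trials,
                            participant = paste0("x", participant))
  expect_error(roc_overlay(d$fit, stranger), "absent from the fit")
  p <- autoplot(ov)
  expect_s3_class(p, "ggplot")
})

test_that("trivial-degenerate inputs are rejected before sampling", {
  spec <- dpsd_population_spec(n_participants = 1,
                               n_trials_per_condition = 12)
  one <- gen_recognition_trials(spec, seed = 1)
  expect_error(fit_dpsd(one), "2 participants")
  two_cond <- gen_recognition_trials(
    dpsd_population_spec(conditions = "A", mean_recollection = 0.3,
                         mean_familiarity = 1, n_participants = 3,
                         n_trials_per_condition = 12), seed = 1)
  expect_error(fit_dpsd(two_cond), "2 conditions")
})
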