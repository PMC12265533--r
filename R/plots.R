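#' Observed and model-predicted ROC series for each participant
#'
#' Pairs each participant's empirical confidence ROC with the smooth ROC
#' implied by their posterior-mean DPSD parameters, giving the
#' plot-ready data behind an individual-level model-fit figure (close
#' agreement between the predicted curves and the observed points
#' indicates good fit).
#'
#' @param fit A [fit_dpsd()] result (with participant draws).
#' @param trials The recognition trials the model was fitted to.
#' @param n_grid Number of criterion values along each predicted curve.
#'
#' @return A tibble of class `roc_overlay` with columns `participant`,
#'   `condition`, `series` (`"observed"`/`"predicted"`), `fa_rate`,
#'   `hit_rate`.
#' @seealso [autoplot.roc_overlay()]
#' @export
roc_overlay <- function(fit, trials, n_grid = 101) {
  stopifnot(inherits(fit, "dpsd_fit"))
  observed <- build_roc(trials) |>
    transmute(participant = as.character(.data$participant),
              condition = as.character(.data$condition),
              series = "observed", fa_rate = .data$fa_rate,
              hit_rate = .data$hit_rate)
  missing <- setdiff(unique(observed$participant), fit$participants)
  if (length(missing) > 0L)
    abort(sprintf("participant(s) absent from the fit: %s",
                  paste(missing, collapse = ", ")))
  grid <- seq(-3, 4, length.out = n_grid)
  predicted <- participant_params(fit) |>
    mutate(series = "predicted",
           curve = pmap(list(.data$recollection, .data$familiarity),
                        function(r, f) {
                          tibble(fa_rate = pnorm(-grid),
                                 hit_rate = r + (1 - r) * pnorm(f - grid))
                        })) |>
    select("participant", "condition", "series", "curve") |>
    tidyr::unnest("curve")
  bind_rows(observed, predicted) |>
    structure(class = c("roc_overlay", "tbl_df", "tbl", "data.frame"))
}

#' Plot observed ROC points with model-predicted curves
#'
#' @param object A [roc_overlay()] tibble.
#' @param ... Unused.
#' @return A ggplot: one panel per participant, observed ROC points
#'   over the posterior-mean predicted curves, colored by condition.
#' @method autoplot roc_overlay
#' @export
autoplot.roc_overlay <- function(object, ...) {
  ggplot(mapping = aes(x = .data$fa_rate, y = .data$hit_rate,
                       color = .data$condition)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                color = "grey60") +
    geom_line(data = filter(object, .data$series == "predicted")) +
    geom_point(data = filter(object, .data$series == "observed"),
               size = 1.2) +
    facet_wrap(~participant) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "False-alarm rate", y = "Hit rate", color = NULL) +
    theme_minimal()
}

#' Plot an individual-level DPSD model-fit figure
#'
#' Convenience wrapper: [roc_overlay()] followed by
#' [autoplot.roc_overlay()].
#'
#' @inheritParams roc_overlay
#' @return A ggplot.
#' @export
plot_fit <- function(fit, trials, n_grid = 101) {
  autoplot(roc_overlay(fit, trials, n_grid))
}

#' Plot empirical confidence ROCs
#'
#' @param object A [build_roc()] result.
#' @param ... Unused.
#' @return A ggplot of the condition-average ROC points.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  avg <- object |>
    group_by(.data$condition, .data$point) |>
    summarise(fa_rate = mean(.data$fa_rate), hit_rate = mean(.data$hit_rate),
              .groups = "drop")
  ggplot(avg, aes(x = .data$fa_rate, y = .data$hit_rate,
                  color = .data$condition)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                color = "grey60") +
    geom_point() + geom_line() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "False-alarm rate", y = "Hit rate", color = NULL) +
    theme_minimal()
}

#' Plot posterior population estimates of a DPSD fit
#'
#' @param object A [fit_dpsd()] result.
#' @param ... Unused.
#' @return A ggplot of posterior means and 95% HDIs for the
#'   population-level recollection and familiarity parameters.
#' @method autoplot dpsd_fit
#' @export
autoplot.dpsd_fit <- function(object, ...) {
  d <- object$summary |>
    filter(.data$parameter %in% c("recollection", "familiarity"))
  ggplot(d, aes(x = .data$condition, y = .data$mean)) +
    geom_pointrange(aes(ymin = .data$hdi_lower, ymax = .data$hdi_upper)) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = NULL, y = "Posterior mean (95% HDI)") +
    theme_minimal()
}

#' Plot CDA amplitude as a function of set size
#'
#' @param object A [compute_cda()] result.
#' @param ... Unused.
#' @return A ggplot of grand-average CDA amplitude (with SEM error
#'   bars) against set size, one line per stimulus type, one panel per
#'   measurement window.
#' @method autoplot cda_result
#' @export
autoplot.cda_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$set_size, y = .data$mean, color = .data$stim_type)) +
    geom_hline(yintercept = 0, color = "grey60") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    geom_line() + geom_point() +
    facet_wrap(~window) +
    scale_x_continuous(breaks = sort(unique(object$summary$set_size))) +
    labs(x = "Set size (items)", y = "CDA amplitude (uV)", color = NULL) +
    theme_minimal()
}

#' Plot grand-average CDA difference waveforms
#'
#' @param x A [compute_cda()] result.
#' @return A ggplot of the contra-minus-ipsi time course per set size,
#'   one panel per stimulus type.
#' @export
plot_cda_timecourse <- function(x) {
  stopifnot(inherits(x, "cda_result"))
  ggplot(x$waveforms,
         aes(x = .data$time, y = .data$amplitude,
             color = factor(.data$set_size))) +
    geom_hline(yintercept = 0, color = "grey60") +
    geom_vline(xintercept = c(0, 1000), linetype = "dotted") +
    geom_line() +
    facet_wrap(~stim_type) +
    labs(x = "Time from array onset (ms)", y = "Contra - ipsi (uV)",
         color = "Set size") +
    theme_minimal()
}
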