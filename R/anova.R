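#' Repeated-measures ANOVA on a table of cell means
#'
#' Fits a one- or two-way within-subject ANOVA on per-participant cell
#' means via `stats::aov()` with the participant error strata
#' (`Error(participant / (A * B))`), and reports F, integer degrees of
#' freedom (no sphericity correction), p and partial eta-squared
#' (`SS_effect / (SS_effect + SS_error)`) per main effect and
#' interaction.  The design must be complete and balanced: exactly one
#' observation per participant per cell.
#'
#' @param data Tibble with one row per participant x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param participant Name of the participant column.
#'
#' @return A tibble with columns `effect`, `df1`, `df2`, `statistic`,
#'   `p.value` and `pes` (partial eta-squared).
#'
#' @examples
#' d <- tidyr::expand_grid(participant = factor(1:6), cond = c("a", "b", "c"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "c")
#' rm_anova(d, dv = "y", within = "cond")
#' @export
rm_anova <- function(data, dv, within, participant = "participant") {
  require_columns(data, c(dv, within, participant), "data")
  if (length(within) < 1L || length(within) > 2L)
    abort("`within` must name one or two factors")
  d <- data |>
    transmute(.p = factor(.data[[participant]]),
              across(all_of(within), ~ factor(.x)),
              .y = .data[[dv]])
  cells <- d |> count(across(all_of(c(".p", within))))
  n_cells <- prod(vapply(d[within], nlevels, 1L))
  if (any(cells$n != 1L) || nrow(cells) != nlevels(d$.p) * n_cells)
    abort("design must be complete and balanced: one value per participant per cell",
          class = "wmcda_design_error")
  if (nlevels(d$.p) < 2L) abort("need at least 2 participants")

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(sprintf(".y ~ %s + Error(.p / (%s))", rhs, rhs))
  fit <- aov(form, data = d)
  strata <- summary(fit)
  # guard for exactly null effects, where aov's 0/0 ratio is meaningless
  eps <- 1e-12 * (sum((d$.y - mean(d$.y))^2) + 1e-300)
  out <- list()
  for (s in strata) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    res <- match("Residuals", terms)
    if (is.na(res)) next
    ss_err <- tab[res, "Sum Sq"]
    df_err <- tab[res, "Df"]
    for (i in setdiff(seq_along(terms), res)) {
      ss_eff <- tab[i, "Sum Sq"]
      row <- tibble(
        effect = gsub("`", "", terms[i]),
        df1 = tab[i, "Df"], df2 = df_err,
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"],
        pes = ss_eff / (ss_eff + ss_err))
      if (ss_eff < eps) {
        row$statistic <- 0
        row$p.value <- 1
        row$pes <- 0
      } else if (ss_err < eps) {
        row$statistic <- Inf
        row$p.value <- 0
        row$pes <- 1
      }
      out[[length(out) + 1L]] <- row
    }
  }
  bind_rows(out)
}

#' Bonferroni-corrected pairwise paired t tests
#'
#' Paired t tests between all level pairs of one within-subject factor,
#' with the p value multiplied by the number of pairs (capped at 1) and
#' Cohen's d computed as the mean difference divided by the standard
#' deviation of the difference scores (so that `d = t / sqrt(n)`).
#'
#' @inheritParams rm_anova
#' @param within Name of the single within-subject factor column.
#'
#' @return A tibble with one row per level pair: `level1`, `level2`,
#'   `statistic` (t), `df`, `p.value`, `p.adj` and `cohens_d`.
#'   Differences are taken as `level1 - level2` in factor-level order.
#' @export
pairwise_tests <- function(data, dv, within, participant = "participant") {
  require_columns(data, c(dv, within, participant), "data")
  wide <- data |>
    transmute(.p = .data[[participant]],
              .lvl = factor(.data[[within]]),
              .y = .data[[dv]]) |>
    pivot_wider(names_from = ".lvl", values_from = ".y")
  lv <- setdiff(names(wide), ".p")
  if (length(lv) < 2L) abort("need at least 2 factor levels")
  if (nrow(wide) < 2L) abort("need at least 2 participants")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  map(pairs, function(pr) {
    diffs <- wide[[pr[1]]] - wide[[pr[2]]]
    if (sd(diffs) == 0)
      abort(sprintf("zero variance of %s - %s differences: paired t is degenerate",
                    pr[1], pr[2]),
            class = "wmcda_degenerate_test")
    tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble(level1 = pr[1], level2 = pr[2],
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value,
           p.adj = min(1, tt$p.value * n_pairs),
           cohens_d = mean(diffs) / sd(diffs))
  }) |> bind_rows()
}
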