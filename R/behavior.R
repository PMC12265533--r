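#' Bin a continuous semicircular confidence response into six levels
#'
#' The recognition probe is answered on a semicircular scale whose two
#' 90-degree response arcs (OLD on the right, NEW on the left) are
#' separated by 90-degree gaps above and below.  Angles are measured in
#' degrees counterclockwise from the rightward horizontal.  The OLD arc
#' spans `[-45, 45)` and is divided, from the bottom up, into
#' surely-old (6), probably-old (5) and guess-old (4); the NEW arc spans
#' `[135, 225)` and is divided into guess-new (3), probably-new (2) and
#' surely-new (1), confidence again increasing toward the bottom of the
#' scale.  A response exactly on a boundary between two bins falls in
#' the lower-numbered bin (the intervals are half-open).
#'
#' @param angle Numeric vector of response angles in degrees; values are
#'   normalized to `[-180, 180)`.
#' @param gap What to do with angles in the unlabeled 90-degree gaps:
#'   `"error"` (default) rejects the response, `"na"` returns `NA`.
#'
#' @return Integer vector of confidence bins in `1:6`
#'   (1 = surely-new ... 6 = surely-old).
#'
#' @examples
#' bin_confidence(c(-30, 0, 30, 150, 180, 210))
#' @export
bin_confidence <- function(angle, gap = c("error", "na")) {
  gap <- match.arg(gap)
  a <- ((angle + 180) %% 360) - 180      # normalize to [-180, 180)
  bin <- rep(NA_integer_, length(a))
  old_arc <- a >= -45 & a < 45
  new_arc <- a >= 135 | a < -135         # [135, 225) wraps past 180
  # OLD side: confidence decreases counterclockwise from the bottom
  bin[old_arc] <- 6L - findInterval(a[old_arc], c(-15, 15))
  # NEW side: map [135, 225) onto [0, 90) then bin the same way
  an <- (a[new_arc] - 135) %% 360
  bin[new_arc] <- 3L - findInterval(an, c(30, 60))
  if (anyNA(bin) && gap == "error") {
    bad <- which(is.na(bin))
    abort(sprintf(
      "response angle(s) fall in the unlabeled gap regions: %s",
      paste(format(angle[head(bad, 5)]), collapse = ", ")),
      class = "wmcda_rejected_response")
  }
  bin
}

#' Tabulate 6-bin confidence responses per participant and condition
#'
#' @param trials Tibble of recognition trials with columns
#'   `participant`, `condition`, `probe_status` and `bin`.
#' @return A tibble of counts with one row per participant x condition x
#'   probe status x bin (all six bins present, zeros included).
#' @export
count_responses <- function(trials) {
  require_columns(trials, c("participant", "condition", "probe_status", "bin"),
                  "trials")
  trials |>
    count(.data$participant, .data$condition, .data$probe_status, .data$bin) |>
    tidyr::complete(.data$participant, .data$condition,
                    probe_status = c("new", "old"), bin = 1:6,
                    fill = list(n = 0L)) |>
    arrange(.data$participant, .data$condition, .data$probe_status, .data$bin)
}

#' Hit rate, false-alarm rate and Cowan's K per design cell
#'
#' Computes per-cell hit rates (signal trials answered "signal"),
#' false-alarm rates (noise trials answered "signal") and the
#' single-probe capacity estimate Cowan's K = set size x (hit rate -
#' false-alarm rate).  Two trial schemas are accepted:
#'
#' * recognition: columns `probe_status` (`"old"`/`"new"`) and `bin`
#'   (1-6); any bin >= 4 (the OLD half of the scale) counts as an "old"
#'   response;
#' * change detection: logical columns `change` and `said_change`.
#'
#' Cells are `participant` crossed with whichever of `condition`,
#' `stim_type` and `set_size` are present.  Rates are formed from
#' integer counts, and K may be negative for below-chance cells.
#'
#' @param trials Trial tibble in one of the schemas above.
#' @param n_items Set size used for K when no `set_size` column exists.
#'
#' @return A tibble with one row per cell: the grouping columns plus
#'   `n_signal`, `n_noise`, `hit_rate`, `fa_rate` and `k`.
#'
#' @examples
#' trials <- tibble::tibble(
#'   participant = "p01", condition = "OBJ_UNI",
#'   probe_status = rep(c("old", "new"), each = 100),
#'   bin = c(rep(6, 72), rep(1, 28), rep(6, 13), rep(1, 87)))
#' compute_rates(trials, n_items = 6)   # k = 6 * (0.72 - 0.13) = 3.54
#' @export
compute_rates <- function(trials, n_items = NULL) {
  require_columns(trials, "participant", "trials")
  if ("bin" %in% names(trials)) {
    require_columns(trials, c("probe_status", "bin"), "trials")
    if (!all(trials$probe_status %in% c("old", "new")))
      abort("probe_status must be 'old' or 'new'", class = "wmcda_schema_error")
    trials <- trials |>
      mutate(.signal = .data$probe_status == "old",
             .said = .data$bin >= 4L)
  } else {
    require_columns(trials, c("change", "said_change"), "trials")
    trials <- trials |>
      mutate(.signal = .data$change, .said = .data$said_change)
  }
  group_cols <- intersect(c("participant", "condition", "stim_type",
                            "set_size"), names(trials))
  if (!"set_size" %in% group_cols) {
    if (is.null(n_items))
      abort("supply `n_items` when trials have no set_size column",
            class = "wmcda_schema_error")
    trials$set_size <- n_items
    group_cols <- c(group_cols, "set_size")
  }
  out <- trials |>
    group_by(across(all_of(group_cols))) |>
    summarise(n_signal = sum(.data$.signal),
              n_noise = sum(!.data$.signal),
              n_hit = sum(.data$.signal & .data$.said),
              n_fa = sum(!.data$.signal & .data$.said),
              .groups = "drop")
  empty <- out$n_signal == 0L | out$n_noise == 0L
  if (any(empty)) {
    cell <- out[which(empty)[1], group_cols]
    abort(sprintf("cell %s has no %s trials",
                  paste(unlist(lapply(cell, as.character)), collapse = "/"),
                  if (out$n_signal[which(empty)[1]] == 0L) "signal" else "noise"),
          class = "wmcda_empty_cell")
  }
  out |>
    mutate(hit_rate = .data$n_hit / .data$n_signal,
           fa_rate = .data$n_fa / .data$n_noise,
           k = .data$set_size * (.data$hit_rate - .data$fa_rate)) |>
    select(all_of(group_cols), "n_signal", "n_noise", "hit_rate", "fa_rate",
           "k")
}

#' Empirical confidence ROC per participant and condition
#'
#' Builds the five cumulative (false-alarm rate, hit rate) points of the
#' confidence ROC, ordered from the strictest criterion (surely-old
#' responses only) to the most lenient (everything but surely-new):
#' point `i` is the proportion of responses in bins `{6, ..., 7 - i}`
#' among old trials (hit rate) and new trials (false-alarm rate).
#'
#' @param trials Recognition trial tibble with `participant`,
#'   `condition`, `probe_status` and `bin`.
#' @return A tibble of class `roc_curve` with columns `participant`,
#'   `condition`, `point` (1-5, strictest first), `fa_rate`, `hit_rate`,
#'   `n_old` and `n_new`.
#' @export
build_roc <- function(trials) {
  counts <- count_responses(trials)
  totals <- counts |>
    group_by(.data$participant, .data$condition, .data$probe_status) |>
    summarise(total = sum(.data$n), .groups = "drop")
  if (any(totals$total == 0L)) {
    bad <- totals[totals$total == 0L, ][1, ]
    abort(sprintf("no %s trials for %s/%s", bad$probe_status,
                  bad$participant, bad$condition),
          class = "wmcda_empty_cell")
  }
  counts |>
    group_by(.data$participant, .data$condition, .data$probe_status) |>
    arrange(desc(.data$bin), .by_group = TRUE) |>
    mutate(cum_rate = cumsum(.data$n) / sum(.data$n),
           point = 7L - .data$bin,
           total = sum(.data$n)) |>
    ungroup() |>
    filter(.data$point >= 1L, .data$point <= 5L) |>
    select("participant", "condition", "probe_status", "point", "cum_rate",
           "total") |>
    pivot_wider(names_from = "probe_status",
                values_from = c("cum_rate", "total")) |>
    transmute(.data$participant, .data$condition, .data$point,
              fa_rate = .data$cum_rate_new, hit_rate = .data$cum_rate_old,
              n_old = .data$total_old, n_new = .data$total_new) |>
    arrange(.data$participant, .data$condition, .data$point) |>
    structure(class = c("roc_curve", "tbl_df", "tbl", "data.frame"))
}
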