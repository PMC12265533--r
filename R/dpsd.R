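#' Dual-process signal-detection parameters for one condition
#'
#' The DPSD model describes confidence-rating recognition as a mixture
#' of two independent processes: all-or-none recollection, which with
#' probability `recollection` drives a maximal-confidence "old"
#' response, and a continuous familiarity signal drawn from a
#' unit-variance normal at distance `familiarity` from the new-item
#' distribution, binned by five ordered criteria.
#'
#' @param recollection Recollection probability in `[0, 1]`.
#' @param familiarity Familiarity strength (standard-normal-distance
#'   units).
#' @param criteria Five strictly increasing criteria on the familiarity
#'   axis.
#'
#' @return An object of class `dpsd_params`.
#' @seealso [dpsd_predict()], [dpsd_loglik()]
#' @export
dpsd_params <- function(recollection, familiarity, criteria) {
  check_prob(recollection, "recollection", 1L)
  if (!is.numeric(familiarity) || length(familiarity) != 1L)
    stop_field("familiarity", "must be a single number")
  if (length(criteria) != 5L) stop_field("criteria", "must have length 5")
  check_increasing(criteria, "criteria")
  structure(list(recollection = recollection, familiarity = familiarity,
                 criteria = criteria),
            class = "dpsd_params")
}

#' @export
print.dpsd_params <- function(x, ...) {
  cat(sprintf("<dpsd_params> R = %.3f, F = %.3f\n  criteria: %s\n",
              x$recollection, x$familiarity,
              paste(format(x$criteria), collapse = " ")))
  invisible(x)
}

#' Predicted ROC of the DPSD model
#'
#' Closed-form cumulative hit and false-alarm rates at each criterion:
#' `hit_rate_i = R + (1 - R) * pnorm(F - c_i)` and
#' `fa_rate_i = pnorm(-c_i)`.  Both sequences decrease in `c_i`, so the
#' row for the largest criterion is the strictest ROC point.
#'
#' @param params A [dpsd_params()] object (or a list with fields
#'   `recollection`, `familiarity`, `criteria`).
#'
#' @return A tibble with columns `criterion` (1-5, most lenient first,
#'   matching the order of `criteria`), `c`, `fa_rate` and `hit_rate`.
#'
#' @examples
#' p <- dpsd_params(0.35, 1.10, c(-1, -0.5, 0, 0.5, 1))
#' dpsd_predict(p)
#' @export
dpsd_predict <- function(params) {
  if (!inherits(params, "dpsd_params"))
    params <- dpsd_params(params$recollection, params$familiarity,
                          params$criteria)
  tibble(criterion = 1:5,
         c = params$criteria,
         fa_rate = pnorm(-params$criteria),
         hit_rate = params$recollection +
           (1 - params$recollection) * pnorm(params$familiarity -
                                               params$criteria))
}

# per-bin response probabilities (bins 1..6, 1 = surely-new);
# rows "new", "old"
dpsd_bin_probs <- function(params) {
  pred <- dpsd_predict(params)
  cum_old <- c(1, pred$hit_rate)   # P(bin > k) at c_0 = -Inf .. c_5
  cum_new <- c(1, pred$fa_rate)
  rbind(new = -diff(c(cum_new, 0)),
        old = -diff(c(cum_old, 0)))
}

#' Multinomial log-likelihood of a 2 x 6 confidence table under DPSD
#'
#' Bin probabilities are successive differences of the cumulative DPSD
#' hit-rate and false-alarm-rate functions (bin 6 = beyond the strictest
#' criterion); the log-likelihood is the sum of two multinomial log
#' probability masses, one over old-trial counts and one over new-trial
#' counts.  Degenerate parameter values that put zero probability on an
#' observed bin yield `-Inf` rather than an error.
#'
#' @inheritParams dpsd_predict
#' @param counts 2 x 6 matrix of response counts with rows `new` and
#'   `old` and columns bins 1-6, or a tibble with columns
#'   `probe_status`, `bin` and `n`.
#'
#' @return A single log-likelihood value (possibly `-Inf`).
#' @export
dpsd_loglik <- function(params, counts) {
  counts <- as_count_matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  p <- dpsd_bin_probs(params)
  p[p < 0] <- 0                          # clip numeric round-off
  ll <- 0
  for (row in c("new", "old")) {
    x <- counts[row, ]
    if (any(x > 0 & p[row, ] <= 0)) return(-Inf)
    ll <- ll + dmultinom(x, prob = p[row, ], log = TRUE)
  }
  ll
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == 2L, ncol(counts) == 6L)
    if (is.null(rownames(counts))) rownames(counts) <- c("new", "old")
    return(counts[c("new", "old"), , drop = FALSE])
  }
  require_columns(counts, c("probe_status", "bin", "n"), "counts")
  m <- matrix(0, 2, 6, dimnames = list(c("new", "old"), 1:6))
  for (i in seq_len(nrow(counts)))
    m[counts$probe_status[i], counts$bin[i]] <-
      m[counts$probe_status[i], counts$bin[i]] + counts$n[i]
  m
}
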