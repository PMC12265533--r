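#' Shortest highest-density interval of a sample
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Probability mass the interval must contain.
#' @return Named numeric vector `c(lower, upper)` — the shortest
#'   contiguous interval containing `prob` of the draws.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  m <- ceiling(prob * n)
  if (n < 2L || m < 1L || m > n)
    abort("too few draws for the requested interval")
  if (m == n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half and the classical potential-scale-
#' reduction factor is computed over the resulting half-chains, so that
#' within-chain drift also inflates the diagnostic.  Values near 1
#' indicate convergence.
#'
#' @param draws Matrix of draws, iterations x chains (a single chain may
#'   be passed as a vector).
#' @return The split-chain R-hat (1 for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) abort("need at least 4 iterations per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[1:half, j], draws[(n - half + 1):n, j])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Summarize posterior draws
#'
#' Posterior mean, shortest 95% highest-density interval, split-chain
#' R-hat and effective sample size for one scalar parameter.
#'
#' @param draws Iterations x chains matrix (or vector) of draws.
#' @param prob HDI probability mass.
#' @return A one-row tibble: `mean`, `hdi_lower`, `hdi_upper`, `rhat`,
#'   `ess`.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  draws <- as.matrix(draws)
  if (length(draws) < 2L) abort("need at least 2 draws")
  h <- hdi(as.vector(draws), prob)
  ess <- tryCatch(
    sum(vapply(seq_len(ncol(draws)),
               function(j) unname(coda::effectiveSize(draws[, j])), 1.0)),
    error = function(e) NA_real_)
  tibble(mean = mean(draws), hdi_lower = unname(h[1]),
         hdi_upper = unname(h[2]),
         rhat = if (nrow(draws) >= 4L) split_rhat(draws) else NA_real_,
         ess = ess)
}
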