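# Brute-force reference implementations, kept deliberately literal and
# independent of the package internals.

oracle_step_flag <- function(v, w, step, thr) {
  n <- length(v)
  half <- w %/% 2
  st <- 1
  while (st + w - 1 <= n) {
    first <- mean(v[st:(st + half - 1)])
    second <- mean(v[(st + w - half):(st + w - 1)])
    if (abs(second - first) > thr) return(TRUE)
    st <- st + step
  }
  FALSE
}

oracle_p2p_flag <- function(v, w, step, thr) {
  n <- length(v)
  st <- 1
  while (st + w - 1 <= n) {
    seg <- v[st:(st + w - 1)]
    if (max(seg) - min(seg) > thr) return(TRUE)
    st <- st + step
  }
  FALSE
}

oracle_abs_flag <- function(v, lim) any(abs(v) > lim)

oracle_drift_flag <- function(v, slope_lim, r2_min) {
  d <- data.frame(t = seq_along(v), v = v)
  fit <- lm(v ~ t, data = d)
  change <- abs(coef(fit)[["t"]]) * (length(v) - 1)
  r2 <- summary(fit)$r.squared
  change > slope_lim && r2 >= r2_min
}

oracle_flat_flag <- function(v) max(v) == min(v)

# sums-of-squares decomposition for balanced within-subject designs;
# returns F per effect, tested against its participant-by-effect stratum
oracle_rm_anova <- function(d, dv, within, participant = "participant") {
  d[[participant]] <- factor(d[[participant]])
  for (f in within) d[[f]] <- factor(d[[f]])
  y <- d[[dv]]
  grand <- mean(y)
  cell_mean <- function(cols) {
    ave(y, d[cols], FUN = mean)
  }
  n <- nrow(d)
  ss <- function(x) sum((x - grand)^2)
  out <- list()
  if (length(within) == 1L) {
    a <- within[1]
    ss_a <- ss(cell_mean(a))
    ss_p <- ss(cell_mean(participant))
    ss_tot <- sum((y - grand)^2)
    ss_err <- ss_tot - ss_a - ss_p
    df_a <- nlevels(d[[a]]) - 1
    df_err <- df_a * (nlevels(d[[participant]]) - 1)
    out[[a]] <- c(F = (ss_a / df_a) / (ss_err / df_err), df1 = df_a,
                  df2 = df_err, pes = ss_a / (ss_a + ss_err))
  } else {
    a <- within[1]; b <- within[2]
    ss_a <- ss(cell_mean(a))
    ss_b <- ss(cell_mean(b))
    ss_p <- ss(cell_mean(participant))
    ss_ab <- ss(cell_mean(c(a, b))) - ss_a - ss_b
    ss_pa <- ss(cell_mean(c(participant, a))) - ss_p - ss_a
    ss_pb <- ss(cell_mean(c(participant, b))) - ss_p - ss_b
    ss_tot <- sum((y - grand)^2)
    ss_pab <- ss_tot - ss_a - ss_b - ss_ab - ss_p - ss_pa - ss_pb
    np <- nlevels(d[[participant]]); na <- nlevels(d[[a]]); nb <- nlevels(d[[b]])
    eff <- function(ss_eff, df_eff, ss_err, df_err) {
      c(F = (ss_eff / df_eff) / (ss_err / df_err), df1 = df_eff,
        df2 = df_err, pes = ss_eff / (ss_eff + ss_err))
    }
    out[[a]] <- eff(ss_a, na - 1, ss_pa, (na - 1) * (np - 1))
    out[[b]] <- eff(ss_b, nb - 1, ss_pb, (nb - 1) * (np - 1))
    out[[paste0(a, ":", b)]] <-
      eff(ss_ab, (na - 1) * (nb - 1), ss_pab, (na - 1) * (nb - 1) * (np - 1))
  }
  out
}
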