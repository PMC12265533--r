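test_that("a null effect yields F = 0", {
  d <- tidyr::expand_grid(participant = factor(1:5), cond = c("a", "b", "c"))
  base <- stats::rnorm(5)
  d$y <- base[as.integer(d$participant)]        # identical across levels
  tab <- rm_anova(d, dv = "y", within = "cond")
  expect_equal(tab$statistic, 0)
})

test_that("two-level RM-ANOVA F equals the squared paired t statistic", {
  withr::with_seed(21, {
    d <- tidyr::expand_grid(participant = factor(1:4), cond = c("a", "b"))
    d$y <- stats::rnorm(8)
    tab <- rm_anova(d, dv = "y", within = "cond")
    wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
    tt <- stats::t.test(wide$a, wide$b, paired = TRUE)
    expect_equal(tab$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(tab$p.value, tt$p.value, tolerance = 1e-10)
  })
})

test_that("one- and two-way tables match the sums-of-squares oracle", {
  withr::with_seed(22, {
    for (i in 1:5) {
      d1 <- tidyr::expand_grid(participant = factor(1:6), cond = letters[1:3])
      d1$y <- stats::rnorm(nrow(d1)) + as.integer(factor(d1$cond)) * 0.5
      tab <- rm_anova(d1, dv = "y", within = "cond")
      orc <- oracle_rm_anova(d1, "y", "cond")
      expect_equal(tab$statistic, unname(orc$cond["F"]), tolerance = 1e-10)
      expect_equal(tab$pes, unname(orc$cond["pes"]), tolerance = 1e-10)
      expect_equal(tab$df1, unname(orc$cond["df1"]))
      expect_equal(tab$df2, unname(orc$cond["df2"]))

      d2 <- tidyr::expand_grid(participant = factor(1:6),
                               a = c("x", "y"), b = c("1", "3", "5"))
      d2$y <- stats::rnorm(nrow(d2)) + (d2$a == "x") * as.integer(d2$b)
      tab2 <- rm_anova(d2, dv = "y", within = c("a", "b"))
      orc2 <- oracle_rm_anova(d2, "y", c("a", "b"))
      for (eff in c("a", "b", "a:b")) {
        row <- tab2[tab2$effect == eff, ]
        expect_equal(row$statistic, unname(orc2[[eff]]["F"]),
                     tolerance = 1e-10)
        expect_equal(row$pes, unname(orc2[[eff]]["pes"]), tolerance = 1e-10)
        expect_equal(row$df2, unname(orc2[[eff]]["df2"]))
      }
    }
  })
})

test_that("incomplete designs are rejected", {
  d <- tidyr::expand_grid(participant = factor(1:4), cond = c("a", "b"))
  d$y <- stats::rnorm(8)
  expect_error(rm_anova(d[-1, ], dv = "y", within = "cond"),
               class = "wmcda_design_error")
})

test_that("pairwise tests apply the Bonferroni factor and cap p at 1", {
  withr::with_seed(23, {
    d <- tidyr::expand_grid(participant = factor(1:8), cond = c("a", "b", "c"))
    d$y <- stats::rnorm(nrow(d)) + (d$cond == "c")
    out <- pairwise_tests(d, dv = "y", within = "cond")
    expect_equal(nrow(out), 3)
    expect_equal(out$p.adj, pmin(1, out$p.value * 3))
    expect_true(all(out$p.adj <= 1))
  })
})

test_that("pairwise t and Cohen's d match direct formula evaluation", {
  d <- tidyr::expand_grid(participant = factor(1:6), cond = c("a", "b"))
  d$y <- c(5.1, 4.2, 6.3, 5.0, 4.8, 5.9, 4.0, 4.1, 5.2, 4.9, 4.1, 4.6)[
    order(rep(1:6, each = 2))]
  wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
  diffs <- wide$a - wide$b
  out <- pairwise_tests(d, dv = "y", within = "cond")
  expect_equal(out$statistic,
               mean(diffs) / (sd(diffs) / sqrt(length(diffs))),
               tolerance = 1e-12)
  expect_equal(out$cohens_d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_equal(out$cohens_d, out$statistic / sqrt(6), tolerance = 1e-12)
  expect_equal(out$df, 5)
})

test_that("zero-variance differences raise a degenerate-test error", {
  d <- tidyr::expand_grid(participant = factor(1:5), cond = c("a", "b"))
  d$y <- rep(stats::rnorm(5), each = 2)    # a and b identical per participant
  expect_error(pairwise_tests(d, dv = "y", within = "cond"),
               class = "wmcda_degenerate_test")
})
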