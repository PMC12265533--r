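test_that("bin_confidence maps arc centers to their labeled bins", {
  # OLD arc [-45, 45): surely/probably/guess-old from the bottom up
  expect_identical(bin_confidence(c(-30, 0, 30)), c(6L, 5L, 4L))
  # NEW arc [135, 225): guess/probably/surely-new
  expect_identical(bin_confidence(c(150, 180, 210)), c(3L, 2L, 1L))
  expect_identical(bin_confidence(-150), 1L)   # 210 expressed as negative
})

test_that("bin boundaries fall into the lower-numbered bin", {
  expect_identical(bin_confidence(c(-15, 15)), c(5L, 4L))
  expect_identical(bin_confidence(c(165, 195)), c(2L, 1L))
})

test_that("angles in the gap regions are rejected", {
  expect_error(bin_confidence(90), class = "wmcda_rejected_response")
  expect_error(bin_confidence(c(0, 60)), class = "wmcda_rejected_response")
  expect_identical(bin_confidence(90, gap = "na"), NA_integer_)
})

test_that("compute_rates reproduces the trial-unique capacity estimate", {
  # H = 0.72, FA = 0.13 at set size 6: K = 6 * 0.59 = 3.54
  rates <- compute_rates(rates_fixture(0.72, 0.13), n_items = 6)
  expect_equal(rates$hit_rate, 0.72)
  expect_equal(rates$fa_rate, 0.13)
  expect_equal(rates$k, 3.54)
})

test_that("K is zero at H = FA and maximal at perfect accuracy", {
  expect_equal(compute_rates(rates_fixture(0.4, 0.4), n_items = 6)$k, 0)
  expect_equal(compute_rates(rates_fixture(1, 0), n_items = 5)$k, 5)
})

test_that("the K identity holds to machine precision on random tables", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      trials <- tibble::tibble(
        participant = "p01", condition = "A",
        probe_status = rep(c("old", "new"), each = n),
        bin = sample(1:6, 2 * n, replace = TRUE))
      r <- compute_rates(trials, n_items = 6)
      expect_equal(r$k, 6 * (r$hit_rate - r$fa_rate))
      expect_true(r$hit_rate >= 0 && r$hit_rate <= 1)
    }
  })
})

test_that("empty cells are rejected with the cell named", {
  trials <- tibble::tibble(participant = "p09", condition = "A",
                           probe_status = "old", bin = 6L)
  expect_error(compute_rates(trials, n_items = 6),
               class = "wmcda_empty_cell")
  expect_error(compute_rates(trials, n_items = 6), "p09")
})

test_that("build_roc matches hand cumulation", {
  old_counts <- c(40, 20, 10, 10, 10, 30)   # bins 6 down to 1, 120 trials
  new_counts <- c(6, 6, 12, 24, 30, 42)
  trials <- tibble::tibble(
    participant = "p01", condition = "A",
    probe_status = rep(c("old", "new"), each = 120),
    bin = c(rep(6:1, old_counts), rep(6:1, new_counts)))
  roc <- build_roc(trials)
  expect_equal(roc$hit_rate, cumsum(old_counts)[1:5] / 120)
  expect_equal(roc$hit_rate, c(1 / 3, 1 / 2, 7 / 12, 2 / 3, 3 / 4))
  expect_equal(roc$fa_rate, cumsum(new_counts)[1:5] / 120)
})

test_that("degenerate ROCs behave as expected", {
  all6 <- tibble::tibble(participant = "p01", condition = "A",
                         probe_status = rep(c("old", "new"), each = 10),
                         bin = 6L)
  roc <- build_roc(all6)
  expect_true(all(roc$hit_rate == 1) && all(roc$fa_rate == 1))
  sym <- tibble::tibble(participant = "p01", condition = "A",
                        probe_status = rep(c("old", "new"), each = 60),
                        bin = rep(rep(1:6, each = 10), 2))
  roc <- build_roc(sym)
  expect_equal(roc$hit_rate, roc$fa_rate)
})

test_that("ROC points are non-decreasing for arbitrary inputs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      trials <- tibble::tibble(
        participant = "p01", condition = "A",
        probe_status = rep(c("old", "new"), c(50, 70)),
        bin = sample(1:6, 120, replace = TRUE,
                     prob = stats::runif(6)))
      roc <- build_roc(trials)
      expect_true(all(diff(roc$hit_rate) >= 0))
      expect_true(all(diff(roc$fa_rate) >= 0))
    }
  })
})
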