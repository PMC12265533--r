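test_that("EOG detectors flag plateau and step artifacts at the printed thresholds", {
  ep <- make_epochs(4)
  veog <- match("VEOG", ep$channels)
  heog <- match("HEOG", ep$channels)
  ep$data[2, veog, 300:500] <- 60          # 60 uV plateau > 50 uV
  ep$data[3, heog, 600:1100] <- 40         # 40 uV instantaneous step > 30 uV
  flags <- detect_eog(ep)
  expect_equal(flags$eog_abs, c(FALSE, TRUE, FALSE, FALSE))
  # the plateau's onset edge is itself a step; the 40 uV step only trips
  # the step detector
  expect_equal(flags$eog_step, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a slow ramp on EOG is not step-flagged but survives the exhaustive scan", {
  ep <- make_epochs(1)
  veog <- match("VEOG", ep$channels)
  n <- dim(ep$data)[3]
  ep$data[1, veog, ] <- seq(0, 100, length.out = n)   # 100 uV over 2200 ms
  flags <- detect_eog(ep)
  expect_false(flags$eog_step[1])
  # brute-force every window: per-window half-difference stays below 30 uV
  expect_false(oracle_step_flag(ep$data[1, veog, ], 50, 5, 30))
  expect_true(flags$eog_abs[1])            # the ramp does exceed 50 uV
})

test_that("gaze steps are flagged above but not below half a degree", {
  ep <- make_epochs(3, channels = c("P3", "P4", "P7", "P8", "PO3", "PO4",
                                    "PO7", "PO8", "VEOG", "HEOG",
                                    "GAZE_X", "GAZE_Y"))
  gx <- match("GAZE_X", ep$channels)
  ep$data[2, gx, 500:1100] <- 1.0
  ep$data[3, gx, 500:1100] <- 0.4
  flags <- detect_gaze(ep)
  expect_equal(flags$gaze, c(FALSE, TRUE, FALSE))
  expect_message(detect_gaze(make_epochs(1)), "skipping gaze")
})

test_that("drift detection requires both slope and fit quality", {
  ep <- make_epochs(4)
  n <- dim(ep$data)[3]
  ramp <- seq(0, 100, length.out = n)
  ep$data[2, 1, ] <- ramp                           # clean ramp, R^2 = 1
  # find a noise level that pushes R^2 to ~0.2 and verify with lm()
  withr::with_seed(61, {
    noise <- stats::rnorm(n)
    target_var <- var(ramp) * (1 - 0.2) / 0.2
    noisy <- ramp + noise * sqrt(target_var) / sd(noise)
  })
  expect_lt(summary(lm(noisy ~ seq_len(n)))$r.squared, 0.3)
  ep$data[3, 1, ] <- noisy
  flags <- detect_drift(ep)
  expect_equal(flags, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("peak-to-peak flags fast excursions but not slow ramps", {
  ep <- make_epochs(3)
  n <- dim(ep$data)[3]
  ep$data[2, 1, 500:525] <- 80                     # 80 uV, 50-ms spike
  ep$data[3, 1, ] <- seq(0, 100, length.out = n)   # < 75 uV per 200-ms window
  flags <- detect_p2p(ep)
  expect_equal(flags, c(FALSE, TRUE, FALSE))
})

test_that("extreme values, DC steps and flatlines are caught", {
  ep <- make_epochs(4)
  ep$data[, , ] <- stats::rnorm(length(ep$data), 0, 2)
  ep$data[1, 2, 400] <- 120                        # beyond +/-100 uV
  ep$data[2, 3, 550:1100] <- ep$data[2, 3, 550:1100] + 70   # 70 uV DC shift
  ep$data[3, 4, ] <- 0                             # dead channel
  flags <- detect_abs_and_steps(ep)
  expect_equal(flags$abs_volt, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags$eeg_step, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(flags$flatline, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("every detector agrees exactly with the brute-force oracle on random epochs", {
  withr::with_seed(62, {
    channels <- c("P3", "P4", "VEOG", "HEOG")
    ep <- make_epochs(30, channels = channels)
    n <- dim(ep$data)[3]
    # heavy-tailed noise plus occasional ramps/steps so both outcomes occur
    for (tr in seq_len(30)) {
      for (ch in 1:4) {
        v <- stats::rnorm(n, 0, sample(c(10, 25, 40), 1))
        if (stats::runif(1) < 0.3)
          v <- v + seq(0, stats::runif(1, -120, 120), length.out = n)
        if (stats::runif(1) < 0.3) {
          at <- sample(n - 100, 1)
          v[at:n] <- v[at:n] + stats::runif(1, -80, 80)
        }
        ep$data[tr, ch, ] <- v
      }
    }
    eog_idx <- 3:4
    eeg_idx <- 1:2
    eog <- detect_eog(ep)
    gotten_abs <- detect_abs_and_steps(ep)
    drift <- detect_drift(ep)
    p2p <- detect_p2p(ep)
    for (tr in seq_len(30)) {
      expect_equal(eog$eog_abs[tr], any(vapply(eog_idx, function(ch)
        oracle_abs_flag(ep$data[tr, ch, ], 50), TRUE)))
      expect_equal(eog$eog_step[tr], any(vapply(eog_idx, function(ch)
        oracle_step_flag(ep$data[tr, ch, ], 50, 5, 30), TRUE)))
      expect_equal(gotten_abs$abs_volt[tr], any(vapply(eeg_idx, function(ch)
        oracle_abs_flag(ep$data[tr, ch, ], 100), TRUE)))
      expect_equal(gotten_abs$eeg_step[tr], any(vapply(eeg_idx, function(ch)
        oracle_step_flag(ep$data[tr, ch, ], 75, 5, 60), TRUE)))
      expect_equal(gotten_abs$flatline[tr], any(vapply(eeg_idx, function(ch)
        oracle_flat_flag(ep$data[tr, ch, ]), TRUE)))
      expect_equal(drift[tr], any(vapply(eeg_idx, function(ch)
        oracle_drift_flag(ep$data[tr, ch, ], 75, 0.3), TRUE)))
      expect_equal(p2p[tr], any(vapply(eeg_idx, function(ch)
        oracle_p2p_flag(ep$data[tr, ch, ], 100, 50, 75), TRUE)))
    }
  })
})

test_that("participants beyond the 30% rejection rate are excluded", {
  # participant A: 7/20 spiked trials (35%); participant B: 1/10 (10%)
  ep <- make_epochs(30, participant = rep(c("A", "B"), c(20, 10)))
  ep$data[, , ] <- stats::rnorm(length(ep$data), 0, 2)
  for (tr in c(1:7, 21)) ep$data[tr, 1, 500:520] <- 150
  res <- reject_and_exclude(ep)
  expect_equal(res$excluded_participants, "A")
  expect_equal(res$retained_participants, "B")
  expect_equal(sum(res$rates$n_rejected), 8)
  # bookkeeping: retained + rejected = total per participant
  expect_equal(res$rates$n_trials - res$rates$n_rejected,
               c(13, 9))
  expect_equal(dim(res$epochs)[1], 9)
  expect_error(reject_and_exclude(ep, max_rate = 0),
               class = "wmcda_all_excluded")
})
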