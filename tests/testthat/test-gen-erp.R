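test_that("epoch geometry matches the sampling spec", {
  spec <- erp_sim_spec(n_participants = 1, n_trials = 1, noise_sd = 0)
  ep <- gen_erp_epochs(spec, seed = 1)
  expect_equal(dim(ep$data)[3], 1100)     # 2200 ms at 500 Hz
  times <- epoch_times(ep)
  expect_equal(times[1], -200)
  expect_equal(times[2] - times[1], 2)
  expect_equal(max(times), 1998)          # half-open [-200, 2000)
})

test_that("noise-free additive spec yields the exact stimulus offset at every set size", {
  spec <- erp_sim_spec(n_participants = 2, n_trials = 2, noise_sd = 0,
                       delta_uv = c(color = 0, object = -1),
                       k_plateau = 3, slope_uv = -0.6)
  cda <- compute_cda(gen_erp_epochs(spec, seed = 1))
  wide <- cda$summary |>
    tidyr::pivot_wider(id_cols = c("set_size", "window"),
                       names_from = "stim_type", values_from = "mean")
  expect_equal(wide$object - wide$color, rep(-1, nrow(wide)))
  combined <- dplyr::filter(cda$summary, window == "combined",
                            stim_type == "color")
  expect_equal(combined$mean[order(combined$set_size)],
               -0.6 * pmin(c(1, 3, 5), 3))
})

test_that("an injected blink exceeds the EOG absolute-voltage threshold", {
  spec <- erp_sim_spec(n_participants = 1, n_trials = 4, noise_sd = 0,
                       artifact_rates = c(blink = 1))
  ep <- gen_erp_epochs(spec, seed = 2)
  veog <- ep$data[, match("VEOG", ep$channels), ]
  expect_true(all(apply(abs(veog), 1, max) > 50))
  flags <- detect_eog(ep)
  expect_true(all(flags$eog_abs))
})

test_that("artifact labels are recorded per class and trial", {
  spec <- erp_sim_spec(n_participants = 1, n_trials = 60, noise_sd = 5,
                       artifact_rates = c(blink = 0.2, step = 0.2))
  ep <- gen_erp_epochs(spec, seed = 3)
  expect_true(all(c("artifact_blink", "artifact_step", "artifact_any") %in%
                    names(ep$trials)))
  expect_equal(ep$trials$artifact_any,
               ep$trials$artifact_blink | ep$trials$artifact_saccade |
                 ep$trials$artifact_drift | ep$trials$artifact_muscle |
                 ep$trials$artifact_step | ep$trials$artifact_flatline)
  expect_gt(sum(ep$trials$artifact_blink), 0)
  expect_gt(sum(ep$trials$artifact_step), 0)
})

test_that("epoch sets round-trip through the plain-text directory format", {
  spec <- erp_sim_spec(n_participants = 1, n_trials = 3, noise_sd = 5,
                       window = c(-200, 400))
  ep <- gen_erp_epochs(spec, seed = 4)
  dir <- withr::local_tempdir()
  write_epoch_set(ep, dir)
  ep2 <- read_epoch_set(dir)
  expect_equal(ep2$channels, ep$channels)
  expect_equal(ep2$srate, ep$srate)
  expect_equal(ep2$window, ep$window)
  expect_equal(unname(ep2$data), unname(ep$data), tolerance = 1e-6)
  expect_equal(ep2$trials$set_size, ep$trials$set_size)
})

test_that("shaped noise has the requested RMS and a red-shifted spectrum", {
  spec <- erp_sim_spec(n_participants = 1, n_trials = 40, noise_sd = 10,
                       noise_exponent = 1)
  ep <- gen_erp_epochs(spec, seed = 5)
  veog <- ep$data[, match("VEOG", ep$channels), ]   # no signal, pure noise
  expect_equal(sd(as.vector(veog)), 10, tolerance = 0.5)
  # low-frequency half of the spectrum should dominate under 1/f shaping
  pw <- apply(veog, 1, function(v) {
    s <- Mod(fft(v))^2
    n <- length(v)
    lo <- sum(s[2:(n %/% 4)])
    hi <- sum(s[(n %/% 4 + 1):(n %/% 2)])
    lo / hi
  })
  expect_gt(median(pw), 2)
})
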