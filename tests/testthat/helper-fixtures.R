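# Small epoch sets built directly in code for detector unit tests.

# zero-filled epoch set: n_trial trials, given channels, 500 Hz
make_epochs <- function(n_trial = 2,
                        channels = c("P3", "P4", "P7", "P8", "PO3", "PO4",
                                     "PO7", "PO8", "VEOG", "HEOG"),
                        window = c(-200, 2000), srate = 500,
                        participant = "p01") {
  n_samp <- round((window[2] - window[1]) * srate / 1000)
  arr <- array(0, dim = c(n_trial, length(channels), n_samp))
  trials <- tibble::tibble(participant = rep_len(participant, n_trial),
                           stim_type = "color",
                           set_size = 3L,
                           cue_side = rep_len(c("left", "right"), n_trial))
  epoch_set(arr, channels, srate, window, trials)
}

# counts table realizing given hit/FA rates exactly over 100 trials each
rates_fixture <- function(hit, fa, n = 100, condition = "OBJ_UNI") {
  stopifnot(hit * n == round(hit * n), fa * n == round(fa * n))
  tibble::tibble(
    participant = "p01", condition = condition,
    probe_status = rep(c("old", "new"), each = n),
    bin = c(rep(6L, hit * n), rep(1L, n - hit * n),
            rep(6L, fa * n), rep(1L, n - fa * n)))
}
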