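test_that("zero amplitude and zero noise give an all-zero epoch", {
  e <- generate_qpc_epoch(10, 14, coupled = TRUE, amp = 0, n_samples = 256,
                          fs = 128, noise_sd = 0, seed = 1)
  expect_equal(e$samples, rep(0, 256))
})

test_that("frequencies outside the Nyquist constraint are rejected", {
  expect_error(generate_qpc_epoch(40, 30, TRUE, 1, 256, fs = 128),
               "f1 \\+ f2")
  expect_error(generate_qpc_epoch(-1, 10, TRUE, 1, 256, fs = 128))
  expect_error(generate_qpc_epoch(10, 14, TRUE, 1, n_samples = 1, fs = 128),
               "n_samples")
})

test_that("phase coupling raises the bispectral peak at the coupling bin", {
  # paired seeds: small realization-averaged direct estimates, coupled vs
  # uncoupled, compared at the (10, 14) Hz bin (bins 10, 14 at nfft = 128)
  nfft <- 128
  m <- non_redundant_mask(nfft)
  at_bin <- function(est) {
    i <- which(m$k1 == 10 & m$k2 == 14)
    Mod(mask_values(est, m))[i]
  }
  avg_est <- function(coupled, block) {
    acc <- NULL
    for (s in 1:8) {
      e <- generate_qpc_epoch(10, 14, coupled, amp = 1, n_samples = nfft,
                              fs = 128, noise_sd = 0,
                              seed = block * 1000 + s)
      b <- bispectrum_direct(e, nfft = nfft, record_len = nfft)
      acc <- if (is.null(acc)) b else { acc$values <- acc$values + b$values; acc }
    }
    acc
  }
  wins <- vapply(1:32, function(block) {
    at_bin(avg_est(TRUE, block)) > at_bin(avg_est(FALSE, block))
  }, logical(1))
  expect_lt(stats::binom.test(sum(wins), 32, alternative = "greater")$p.value,
            0.01)
})

test_that("generate_dataset is deterministic and matches the configured shape", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_emotion = 1,
                      n_channels = 3, trial_seconds = 36, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1$recordings, 2 * 6 * 1)
  expect_true(all(vapply(d1$recordings, function(r) nrow(r$data), 0L) == 3))
  expect_true(all(vapply(d1$recordings, recording_seconds, 0) == 36))
  # different seed changes the data
  d3 <- generate_dataset(synth_config(n_subjects = 2,
                                      n_trials_per_emotion = 1,
                                      n_channels = 3, trial_seconds = 36,
                                      seed = 8))
  expect_false(identical(d1$recordings[[1]]$data, d3$recordings[[1]]$data))
})

test_that("a coupling table missing an emotion is a configuration error", {
  tab <- default_coupling_table()
  expect_error(
    synth_config(coupling_table = tab[tab$emotion != "S", ]),
    "no rows for emotion")
})

test_that("coupling pairs violating f1 + f2 < fs/2 are rejected", {
  tab <- default_coupling_table()
  tab$f1[1] <- 40; tab$f2[1] <- 30
  expect_error(synth_config(coupling_table = tab), "f1 \\+ f2 < fs/2")
})

test_that("blink injection respects rate, amplitude and the clipping contract", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_emotion = 1,
                      n_channels = 4, trial_seconds = 36, noise_sd = 5,
                      blink_rate = 0, seed = 3)
  rec <- generate_dataset(cfg)$recordings[[1]]

  expect_identical(inject_blinks(rec, rate = 0, amp = 120), rec)
  expect_error(inject_blinks(rec, rate = 10, amp = 60), "exceed 80")

  blinked <- inject_blinks(rec, rate = 10, amp = 120, seed = 5)
  expect_gt(max(abs(blinked$data)), 80)
  expect_identical(dim(blinked$data), dim(rec$data))

  clipped <- clip_artifacts(blinked)
  expect_lte(max(abs(clipped$data)), 80)
})

test_that("emotions with identical coupling rows are indistinguishable downstream", {
  # null property: restrict ANOVA to two emotions given identical rows; the
  # p-values over repeated seeds behave like a uniform draw
  tab <- default_coupling_table()
  for (b in unique(tab$band)) {   # make D a copy of A in every band
    ai <- which(tab$emotion == "A" & tab$band == b)
    di <- which(tab$emotion == "D" & tab$band == b)
    tab[di, c("f1", "f2", "amp")] <- tab[ai, c("f1", "f2", "amp")]
  }
  ps <- vapply(1:20, function(s) {
    cfg <- synth_config(n_subjects = 1, n_trials_per_emotion = 2,
                        n_channels = 2, trial_seconds = 36,
                        coupling_table = tab, blink_rate = 0, seed = s)
    d <- generate_dataset(cfg)
    keep <- grepl("_(A|D)_", names(d$recordings))
    ft <- build_feature_table(d$recordings[keep], bands = "alpha",
                              params = bispec_params(nfft = 64, max_lag = 31,
                                                     record_len = 128),
                              n_windows = 1)
    anova_oneway(split(ft$H1, ft$emotion))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
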