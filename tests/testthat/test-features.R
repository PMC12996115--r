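test_that("window segmentation follows the floor-partition count", {
  eeg90 <- eeg_block(matrix(0, 1, 90 * 500), "a", 500)
  expect_equal(n_epochs(segment_windows(eeg90, 0.5)), 180L)

  eeg30 <- eeg_block(matrix(0, 1, 30 * 100), "a", 100)
  expect_equal(n_epochs(segment_windows(eeg30, 30)), 1L)

  # enumerated oracle: starts 0, 2, 4, 6 s fit a 4-s window in 10 s
  eeg10 <- eeg_block(matrix(0, 1, 10 * 100), "a", 100)
  ep <- segment_windows(eeg10, 4, overlap_fraction = 0.5)
  expect_equal(n_epochs(ep), 4L)
  expect_equal(ep$onsets_s, c(0, 2, 4, 6))

  expect_error(segment_windows(eeg10, 11), "window too long")
  expect_error(segment_windows(eeg10, 1, overlap_fraction = 1), "overlap")
})

test_that("Welch PSD locates sinusoid peaks and scales power correctly", {
  fs <- 500
  eeg <- fx_sine_block(10, 1, fs = fs, dur = 4)
  spec <- welch_psd(eeg$samples, fs)
  # FFT oracle: raw periodogram of the same signal puts its peak at the
  # grid frequency nearest 10 Hz
  ft <- abs(stats::fft(eeg$samples[1, ]))^2
  fgrid <- (seq_along(ft) - 1) * fs / length(ft)
  oracle_peak <- fgrid[which.max(ft[fgrid <= fs / 2])]
  expect_equal(spec$freq[which.max(spec$power[1, ])], oracle_peak)
  # unit-amplitude sinusoid carries 0.5 uV^2 of power
  total <- pracma::trapz(spec$freq, spec$power[1, ])
  expect_equal(total, 0.5, tolerance = 0.05)

  set.seed(31)
  w <- rnorm(4 * fs)
  p1 <- welch_psd(w, fs)
  p2 <- welch_psd(2 * w, fs)
  expect_equal(pracma::trapz(p2$freq, p2$power[1, ]) /
                 pracma::trapz(p1$freq, p1$power[1, ]), 4, tolerance = 0.1)

  expect_true(all(welch_psd(rep(0, fs), fs)$power == 0))
  expect_error(welch_psd(rnorm(10), fs, seg_len_s = 1), "segment too short")
})

test_that("band powers integrate the spectrum over [low, high)", {
  fs <- 500
  spec <- welch_psd(fx_sine_block(10, 1, fs = fs, dur = 4)$samples, fs)
  bands <- default_bands()
  alpha <- bandpower(spec, bands$alpha)
  total <- pracma::trapz(spec$freq, spec$power[1, ])
  expect_gte(alpha, 0.9 * total)

  parts <- sum(vapply(bands, function(b) bandpower(spec, b), 0))
  expect_lte(parts, total + 1e-9)

  zero <- welch_psd(rep(0, fs), fs)
  expect_equal(bandpower(zero, bands$alpha), 0)
  expect_error(bandpower(spec, band_definition("hf", 300, 400)),
               "band outside spectrum")
})

test_that("the FAA index is ln(R) - ln(L), antisymmetric and zero at equality", {
  expect_equal(faa_index(3, 3), 0)
  expect_equal(faa_index(1, 2), log(2))
  expect_error(faa_index(0, 1), "invalid power")
  set.seed(41)
  for (i in 1:25) {
    l <- runif(1, 0.01, 10); r <- runif(1, 0.01, 10)
    expect_equal(faa_index(l, r), -faa_index(r, l))
  }
})

test_that("calibration features give 4 FAA values plus the window-mean HR", {
  mont <- montage_labels()
  pairs <- default_faa_pairs()
  fs <- 500
  # symmetric alpha on all pair channels, silence elsewhere
  amp <- ifelse(mont %in% c(pairs$left, pairs$right), 10, 1)
  eeg <- fx_sine_block(rep(10, 32), amp, fs = fs, dur = 1, labels = mont)
  ep <- segment_windows(eeg, 0.5)
  hr <- hr_series(c(0.25, 0.75), c(72, 72))
  feats <- calibration_features(ep, hr)
  expect_identical(colnames(feats), fx_feature_names())
  expect_equal(dim(feats), c(2L, 5L))
  expect_equal(as.vector(feats[, 1:4]), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(feats[, "mean_HR"]), c(72, 72))

  # right alpha amplitude halved -> FAA = ln(0.25) on every pair
  amp_r <- ifelse(mont %in% pairs$right, 5, amp)
  eeg_f <- fx_sine_block(rep(10, 32), amp_r, fs = fs, dur = 1, labels = mont)
  f2 <- calibration_features(segment_windows(eeg_f, 0.5), hr)
  expect_equal(as.vector(f2[, 1:4]), rep(2 * log(0.5), 8), tolerance = 0.05)

  small <- fx_sine_block(10, 1, labels = "F3")
  expect_error(calibration_features(segment_windows(small, 0.5), hr),
               "montage mismatch")
})

test_that("offline features emit 160 band powers plus 4 FAA values in fixed order", {
  set.seed(51)
  eeg <- simulate_eeg(0.3, fx_params(), 2)
  ep <- segment_windows(eeg, 2)
  X <- offline_features(ep)
  expect_equal(ncol(X), 164L)
  expect_equal(sum(!grepl("^FAA_", colnames(X))), 160L)
  expect_identical(colnames(X)[1:5],
                   paste0("Fp1_", c("delta", "theta", "alpha", "beta", "gamma")))
  expect_identical(utils::tail(colnames(X), 4), default_faa_pairs()$name)
  expect_true(all(X[, 1:160] >= 0))

  zero <- eeg_block(matrix(0, 32, 1000), montage_labels(), 500)
  expect_error(offline_features(segment_windows(zero, 2)), "invalid power")
  bad <- eeg_block(matrix(0, 8, 1000), paste0("c", 1:8), 500)
  expect_error(offline_features(segment_windows(bad, 2)), "montage mismatch")
})

test_that("PPG heart-rate estimation recovers the generating rate", {
  pp <- participant_params(hr_jitter = 0)
  hr <- simulate_hr(0, pp, 60, ppg = TRUE, seed = 3)
  pg <- attr(hr, "ppg")
  est <- estimate_hr_from_ppg(pg$signal, pg$fs)
  expect_true(all(abs(est$values - 72) <= 1))
  expect_false(any(attr(est, "flagged")))

  # 60 bpm with additive noise at 10 dB SNR
  pp60 <- participant_params(hr_base = 60, hr_jitter = 0)
  hr60 <- simulate_hr(0, pp60, 60, ppg = TRUE, seed = 4)
  pg60 <- attr(hr60, "ppg")
  set.seed(5)
  noisy <- pg60$signal +
    rnorm(length(pg60$signal), 0, sqrt(mean(pg60$signal^2) / 10))
  est60 <- estimate_hr_from_ppg(noisy, pg60$fs)
  expect_true(all(abs(est60$values - 60) <= 2))

  expect_error(estimate_hr_from_ppg(rep(0, 3000), 100), "no usable pulse")
  expect_error(estimate_hr_from_ppg(rep(0, 100), 100), "at least 10 s")
})

test_that("HR aligns to the EEG grid by linear interpolation with held ends", {
  eeg <- eeg_block(matrix(0, 1, 500 * 6), "a", 500)
  const <- align_hr_to_eeg(hr_series(c(1, 4), c(70, 70)), eeg)
  expect_true(all(const == 70))
  expect_length(const, 3000L)

  two <- align_hr_to_eeg(hr_series(c(0, 5), c(60, 70)), eeg)
  expect_equal(two[round(2.5 * 500) + 1], 65)

  set.seed(61)
  t_hr <- sort(sample(seq(0.1, 5.9, by = 1 / 500), 8))  # on the EEG grid
  v_hr <- runif(8, 60, 90)
  walk <- align_hr_to_eeg(hr_series(t_hr, v_hr), eeg)
  at_native <- walk[match(round(t_hr * 500), round(eeg_times(eeg) * 500))]
  expect_equal(at_native, v_hr, tolerance = 1e-9)
})
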