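# Analytic magnitude of the zero-phase order-n digital Butterworth
# bandpass at frequency f: bilinear-prewarped band edges feed the
# lowpass-prototype magnitude; the forward-backward pass squares it.
butter_bandpass_gain <- function(f, low, high, order, fs, zero_phase = TRUE) {
  wl <- tan(pi * low / fs); wh <- tan(pi * high / fs); w <- tan(pi * f / fs)
  om <- (w^2 - wl * wh) / (w * (wh - wl))
  g <- 1 / sqrt(1 + om^(2 * order))
  if (zero_phase) g^2 else g
}

test_that("bandpass has unit passband gain and the analytic stopband attenuation", {
  fs <- 500
  tt <- (0:(10 * fs - 1)) / fs
  mid <- seq(round(length(tt) * 0.2), round(length(tt) * 0.8))
  rms <- function(x) sqrt(mean(x^2))

  e10 <- eeg_block(rbind(sin(2 * pi * 10 * tt)), "ch1", fs)
  y10 <- bandpass_filter(e10)$samples[1, ]
  expect_equal(rms(y10[mid]) / rms(e10$samples[1, mid]), 1, tolerance = 0.02)

  e50 <- eeg_block(rbind(sin(2 * pi * 50 * tt)), "ch1", fs)
  y50 <- bandpass_filter(e50)$samples[1, ]
  atten_db <- -20 * log10(rms(y50[mid]) / rms(e50$samples[1, mid]))
  oracle_db <- -20 * log10(butter_bandpass_gain(50, 1, 40, 4, fs))
  expect_equal(oracle_db, 18.16, tolerance = 0.01)
  expect_equal(atten_db, oracle_db, tolerance = 0.1)
  expect_gt(atten_db, 17)

  zero <- bandpass_filter(eeg_block(matrix(0, 2, fs), c("a", "b"), fs))
  expect_true(all(zero$samples == 0))
  expect_error(bandpass_filter(e10, filter_spec(1, 260)), "invalid filter")
})

test_that("filtering preserves shape and labels and introduces no NaN", {
  set.seed(3)
  eeg <- eeg_block(matrix(rnorm(8 * 2000), 8), paste0("c", 1:8), 500)
  out <- bandpass_filter(eeg)
  expect_identical(dim(out$samples), dim(eeg$samples))
  expect_identical(out$channel_labels, eeg$channel_labels)
  expect_false(anyNA(out$samples))
})

test_that("common average reference zeroes the instantaneous channel mean", {
  two <- eeg_block(matrix(c(1, 3), 2, 1), c("a", "b"), 500)
  expect_equal(as.vector(common_average_reference(two)$samples), c(-1, 1))

  set.seed(11)
  eeg <- eeg_block(matrix(rnorm(32 * 1000, sd = 20), 32),
                   paste0("c", 1:32), 500)
  car <- common_average_reference(eeg)
  expect_lt(max(abs(colMeans(car$samples))), 1e-9)
  expect_equal(common_average_reference(car)$samples, car$samples)

  expect_error(common_average_reference(
    eeg_block(matrix(1, 1, 10), "a", 500)), "CAR undefined")
})

test_that("baseline correction removes the pre-marker channel means", {
  fs <- 100
  mk <- marker_stream(6, "Spider_Scene")
  const <- eeg_block(matrix(7, 1, 10 * fs), "a", fs)
  expect_true(all(baseline_correct(const, mk)$samples == 0))

  tt <- (0:(10 * fs - 1)) / fs
  ac <- sin(2 * pi * 5 * tt)               # zero-mean over the window
  eeg <- eeg_block(rbind(ac + 5, ac - 3), c("a", "b"), fs)
  out <- baseline_correct(eeg, mk)
  expect_lt(max(abs(out$samples - rbind(ac, ac))), 1e-9)

  expect_error(baseline_correct(eeg, marker_stream(2, "Beep")),
               "insufficient baseline")
})

test_that("bad-channel detection flags scaled channels and is scale-equivariant", {
  set.seed(21)
  samples <- matrix(rnorm(32 * 2000), 32)
  samples[17, ] <- samples[17, ] * 50
  eeg <- eeg_block(samples, paste0("c", 1:32), 500)
  qc <- detect_bad_channels(eeg)
  expect_identical(qc$bad_labels, "c17")

  scaled <- eeg_block(samples * 3.7, paste0("c", 1:32), 500)
  expect_equal(detect_bad_channels(scaled)$deviation_score,
               qc$deviation_score)

  same <- eeg_block(matrix(rep(rnorm(100), each = 5), 5, byrow = FALSE),
                    paste0("c", 1:5), 100)
  expect_warning(qc2 <- detect_bad_channels(same), "zero amplitude")
  expect_length(qc2$bad_labels, 0)

  expect_length(detect_bad_channels(eeg, z_threshold = Inf)$bad_labels, 0)
})

test_that("inverse-distance interpolation rebuilds flagged channels", {
  pos <- data.frame(label = c("L", "M", "R"),
                    x = c(-1, 0, 1), y = 0, z = 0)
  eeg <- eeg_block(matrix(c(2, 99, 4), 3, 1), c("L", "M", "R"), 500)
  out <- interpolate_channels(eeg, "M", positions = pos)
  expect_equal(unname(out$samples["M", 1]), 3)  # equidistant neighbors: mean
  expect_equal(unname(out$samples[c("L", "R"), 1]), c(2, 4))

  expect_identical(interpolate_channels(eeg, character(), positions = pos),
                   eeg)
  expect_error(interpolate_channels(eeg, c("L", "M", "R"), positions = pos),
               "all channels bad")

  # smooth spatial field on the real montage: corruption mostly removed
  mont <- montage_1020()
  field <- 5 + 3 * mont$x + 2 * mont$y
  eeg32 <- eeg_block(matrix(field, 32, 10), mont$label, 500)
  corrupted <- eeg32
  corrupted$samples["Cz", ] <- corrupted$samples["Cz", ] + 10
  fixed <- interpolate_channels(corrupted, "Cz")
  err <- max(abs(fixed$samples["Cz", ] - eeg32$samples["Cz", ]))
  expect_lt(err, 10 / 5)
})

test_that("the preprocessing chain composes filter, CAR and baseline", {
  ses <- fx_session(dur = 12, marker_times = 6, marker_labels = "Spider_Scene")
  out <- preprocess_session(ses)
  expect_lt(max(abs(colMeans(out$eeg$samples))), 1e-9)
  expect_identical(dim(out$eeg$samples), dim(ses$eeg$samples))
})
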