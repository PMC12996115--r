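# Shared fixtures, built lazily in code so heavy simulations run once.

.fx <- new.env(parent = emptyenv())

fx_params <- function() participant_params()

# Pretest session, calibration dataset, and trained classifier (cached).
fx_calibration <- function() {
  if (is.null(.fx$model)) {
    ses <- simulate_session(fx_params(), "pretest", seed = 42)
    ds <- build_calibration_dataset(ses)
    .fx$pretest <- ses
    .fx$dataset <- ds
    .fx$model <- train_fear_classifier(ds)
  }
  list(session = .fx$pretest, dataset = .fx$dataset, model = .fx$model)
}

fx_feature_names <- function() {
  c("FAA_F3F4", "FAA_F7F8", "FAA_FC5FC6", "FAA_FT9FT10", "mean_HR")
}

# Hand-built linear classifier with known weights, for exact control of
# signed distances in controller tests.
fx_manual_model <- function(weights = rep(0, 5), rho = 0,
                            center = rep(0, 5), scale = rep(1, 5)) {
  nm <- fx_feature_names()
  structure(list(kernel = "linear", cost = 1, gamma = NA_real_,
                 sv = matrix(0, 1, 5), coefs = 0, rho = rho, sign = 1,
                 weights = weights,
                 scaler = list(center = stats::setNames(center, nm),
                               scale = stats::setNames(scale, nm)),
                 feature_names = nm, training_accuracy = NA_real_),
            class = "fear_classifier")
}

# Multi-sinusoid EEG block: one row per (freq, amp) pair.
fx_sine_block <- function(freqs, amps, fs = 500, dur = 2,
                          labels = paste0("ch", seq_along(freqs)),
                          phases = rep(0, length(freqs))) {
  tt <- (seq_len(round(dur * fs)) - 1L) / fs
  samples <- t(mapply(function(f, a, ph) a * sin(2 * pi * f * tt + ph),
                      freqs, amps, phases))
  eeg_block(samples, labels, fs)
}

# Small synthetic session: sinusoidal EEG, steady HR, optional markers.
fx_session <- function(dur = 10, fs = 500, n_chan = 4, hr_bpm = 72,
                       marker_times = numeric(), marker_labels = character()) {
  set.seed(404)
  tt <- (seq_len(dur * fs) - 1L) / fs
  samples <- t(sapply(seq_len(n_chan), function(i)
    10 * sin(2 * pi * 10 * tt + i) + rnorm(length(tt))))
  eeg <- eeg_block(samples, paste0("ch", seq_len(n_chan)), fs)
  hr_t <- seq(2.5, dur - 0.1, by = 5)
  hr <- hr_series(hr_t, rep(hr_bpm, length(hr_t)))
  session_recording(eeg, hr, marker_stream(marker_times, marker_labels))
}

# Independent brute-force BH step-up: enumerate every candidate k.
bf_benjamini_hochberg <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) / m * alpha)
  rejected <- logical(m)
  if (length(ks)) rejected[o[seq_len(max(ks))]] <- TRUE
  rejected
}
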