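#' Virtual participant simulator
#'
#' Generates synthetic sessions so the whole stack can run without
#' hardware: EEG as 1/f background noise plus band-limited oscillators
#' whose amplitudes respond to a latent fear state (right-frontal alpha
#' suppression, frontal theta increase, global fast-band suppression),
#' heart rate with arousal, habituation and threat-level bradycardia, and
#' subjective ratings quantized from the latent fear. All couplings are
#' synthetic constants chosen to mirror the direction of the empirical
#' effects, and are configurable. Everything is deterministic under a
#' seed (R's default Mersenne-Twister RNG).
#'
#' @name simulator
NULL

#' Virtual participant parameters
#'
#' @param alpha_base baseline alpha oscillator amplitude (uV); default 15.
#' @param asymmetry_gain fractional right-frontal alpha amplitude
#'   suppression per unit fear, in `[0, 1)`; default 0.5. Full fear then
#'   halves right alpha amplitude, i.e. quarters its power, so the
#'   expected FAA is `ln((1 - g f)^2)`.
#' @param hr_base resting heart rate (bpm); default 72.
#' @param hr_arousal_gain bpm added per unit fear; default 15.
#' @param habituation_rate per-iteration multiplicative fear decay in
#'   `[0, 1)`; default 0.05.
#' @param bradycardia_threshold stimulus level above which the freezing
#'   bradycardia term engages; default 3.
#' @param bradycardia_drop bpm subtracted when that threshold is
#'   exceeded; default 8.
#' @param sensitivity logistic slope of fear versus stimulus level;
#'   default 2.
#' @param level_midpoint stimulus level at which fear = 0.5 (before
#'   habituation); default 2.5.
#' @param noise_exponent 1/f spectral slope of the background noise;
#'   default 1.
#' @param noise_scale background noise RMS (uV); default 2.
#' @param band_amplitudes oscillator amplitudes (uV) for delta, theta,
#'   beta, gamma (alpha comes from `alpha_base`).
#' @param hr_jitter Gaussian HR jitter s.d. (bpm); default 1.
#' @param seed RNG seed attached to the participant; `NULL` leaves the
#'   caller's RNG stream untouched.
#' @return a `participant_params` list.
#' @export
participant_params <- function(alpha_base = 15, asymmetry_gain = 0.5,
                               hr_base = 72, hr_arousal_gain = 15,
                               habituation_rate = 0.05,
                               bradycardia_threshold = 3,
                               bradycardia_drop = 8,
                               sensitivity = 2, level_midpoint = 2.5,
                               noise_exponent = 1, noise_scale = 2,
                               band_amplitudes = c(delta = 8, theta = 6,
                                                   beta = 4, gamma = 2),
                               hr_jitter = 1, seed = NULL) {
  if (alpha_base <= 0) stop("alpha_base must be > 0")
  if (asymmetry_gain < 0 || asymmetry_gain >= 1)
    stop("asymmetry_gain must be in [0, 1)")
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  structure(as.list(environment()), class = "participant_params")
}

# Oscillator center frequencies (Hz) per band.
.band_centers <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 35)

# Right-frontal channels carrying the fear-dependent alpha suppression.
.right_frontal <- c("F4", "F8", "FC6", "FT10")

#' Advance the latent fear state
#'
#' `fear = logistic(sensitivity * (level - midpoint)) *
#' (1 - habituation_rate)^iteration`: bounded in `[0, 1]`, monotone
#' non-decreasing in level at fixed iteration, decaying with repeated
#' exposure.
#'
#' @param state a `fear_state` (list with `value`, `level`, `iteration`)
#'   or `NULL` to start at iteration 0.
#' @param level current stimulus level, 1..5.
#' @param params a `participant_params`.
#' @return updated `fear_state` (the iteration counter advances by one).
#' @export
update_fear_state <- function(state, level, params) {
  stopifnot(inherits(params, "participant_params"))
  iter <- if (is.null(state)) 0L else state$iteration
  value <- stats::plogis(params$sensitivity * (level - params$level_midpoint)) *
    (1 - params$habituation_rate)^iter
  structure(list(value = min(1, max(0, value)), level = level,
                 iteration = iter + 1L),
            class = "fear_state")
}

# 1/f^exponent noise via spectral shaping of white noise, scaled to rms.
.pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  w <- stats::rnorm(n)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n          # folded (two-sided) frequency
  shape <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * rms / s
}

#' Simulate a multichannel EEG block
#'
#' Each channel is 1/f background noise plus one sinusoidal oscillator per
#' band (delta/theta/alpha/beta/gamma, random phase per channel). Fear
#' couples in as: right-frontal (F4, F8, FC6, FT10) alpha amplitude scaled
#' by `1 - asymmetry_gain * fear`; frontal theta scaled by
#' `1 + 0.3 * fear`; alpha, beta and gamma globally scaled by
#' `1 - 0.2 * fear`. The global scaling hits both pair channels equally,
#' so the expected FAA is `2 * ln(1 - asymmetry_gain * fear)`.
#'
#' @param fear fear level in `[0, 1]`.
#' @param params a `participant_params`.
#' @param duration_s block length in seconds.
#' @param fs sampling rate; default 500 Hz.
#' @param labels channel labels; default the packaged 32-channel montage.
#' @param t0 block start time; default 0.
#' @param seed optional seed for reproducible samples.
#' @return an `eeg_block`.
#' @export
simulate_eeg <- function(fear, params, duration_s, fs = 500,
                         labels = montage_labels(), t0 = 0, seed = NULL) {
  stopifnot(inherits(params, "participant_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  tt <- (seq_len(n) - 1L) / fs
  amps <- c(params$band_amplitudes["delta"], params$band_amplitudes["theta"],
            alpha = params$alpha_base, params$band_amplitudes["beta"],
            params$band_amplitudes["gamma"])
  names(amps) <- names(.band_centers)
  fast <- c("alpha", "beta", "gamma")
  out <- matrix(0, length(labels), n)
  for (i in seq_along(labels)) {
    ch <- labels[i]
    a <- amps
    a[fast] <- a[fast] * (1 - 0.2 * fear)
    if (startsWith(ch, "F")) a["theta"] <- a["theta"] * (1 + 0.3 * fear)
    if (ch %in% .right_frontal)
      a["alpha"] <- a["alpha"] * (1 - params$asymmetry_gain * fear)
    x <- .pink_noise(n, fs, params$noise_exponent, params$noise_scale)
    phases <- stats::runif(length(.band_centers), 0, 2 * pi)
    for (b in seq_along(.band_centers))
      x <- x + a[b] * sin(2 * pi * .band_centers[b] * tt + phases[b])
    out[i, ] <- x
  }
  eeg_block(out, labels, fs, t0 = t0)
}

#' Simulate a heart-rate series (and optionally a raw PPG waveform)
#'
#' `HR = hr_base + hr_arousal_gain * fear - bradycardia_drop * [level >
#' threshold]` plus Gaussian jitter, reported on the 5-s cadence. With
#' `ppg = TRUE` a raw pulse waveform at the instantaneous rate is
#' synthesized as well (raised-cosine systolic pulses).
#'
#' @param fear fear trajectory: scalar, or vector with one value per 5-s
#'   block.
#' @param params a `participant_params`.
#' @param duration_s series length in seconds.
#' @param level stimulus level trajectory (scalar or per-block vector);
#'   default 1 (no bradycardia).
#' @param ppg also synthesize the raw PPG waveform; default FALSE.
#' @param ppg_fs PPG sampling rate; default 100 Hz.
#' @param t0 start time; default 0.
#' @param seed optional seed.
#' @return an `hr_series`; with `ppg = TRUE`, the waveform is attached as
#'   attribute `"ppg"` (list with `signal`, `fs`).
#' @export
simulate_hr <- function(fear, params, duration_s, level = 1, ppg = FALSE,
                        ppg_fs = 100, t0 = 0, seed = NULL) {
  stopifnot(inherits(params, "participant_params"))
  if (!is.null(seed)) set.seed(seed)
  cadence <- if (duration_s < 5) duration_s else 5
  n_blk <- max(1L, floor(duration_s / cadence))
  fear_blk <- rep_len(fear, n_blk)
  level_blk <- rep_len(level, n_blk)
  hr <- params$hr_base + params$hr_arousal_gain * fear_blk -
    params$bradycardia_drop * (level_blk > params$bradycardia_threshold) +
    stats::rnorm(n_blk, 0, params$hr_jitter)
  hr <- pmin(249, pmax(21, hr))
  out <- hr_series(t0 + (seq_len(n_blk) - 0.5) * cadence, hr,
                   native_interval_s = cadence)
  if (ppg) {
    rate_at <- function(t) hr[pmin(n_blk, pmax(1L, floor(t / cadence) + 1L))]
    beats <- numeric(0)
    t <- 0
    while (t < duration_s) {
      beats <- c(beats, t)
      t <- t + 60 / rate_at(t)
    }
    m <- as.integer(round(duration_s * ppg_fs))
    tt <- (seq_len(m) - 1L) / ppg_fs
    sig <- numeric(m)
    width <- 0.25
    for (b in beats) {
      idx <- which(tt >= b & tt < b + width)
      sig[idx] <- sig[idx] + 0.5 * (1 - cos(2 * pi * (tt[idx] - b) / width))
    }
    attr(out, "ppg") <- list(signal = sig, fs = ppg_fs)
  }
  out
}

# Quantize latent fear into the 4-point finger-rating scale
# (bin edges 0.25/0.5/0.75; boundary values map to the lower rating).
.quantize_rating <- function(fear) as.integer(sum(fear > c(0.25, 0.5, 0.75)) + 1L)

#' Simulate a full session under a protocol
#'
#' `protocol = "pretest"`: `relax_s` of the neutral scene (fear 0), the
#' `Spider_Scene` marker, a `scene_delay_s` transition, the
#' `Spider_Stimulus` marker, and `fear_s` under the maximal stimulus
#' (fear at level 5). `protocol = "main"`: `n_iter` segments of
#' `exposure_s` at the given `levels` trajectory, with `Level_Change`
#' markers at level switches and ratings quantized from the latent fear.
#'
#' @param params a `participant_params`.
#' @param protocol `"pretest"` or `"main"`.
#' @param relax_s,fear_s pretest phase lengths; default 90 s each.
#' @param scene_delay_s gap between scene switch and spider onset;
#'   default 5 s (total pretest length `relax_s + scene_delay_s + fear_s`).
#' @param n_iter,exposure_s main-protocol loop geometry; defaults 10 and
#'   30 s.
#' @param levels main-protocol level trajectory (recycled to `n_iter`);
#'   default constant 3.
#' @param meta metadata list passed into the session.
#' @param seed seed for the whole session; overrides `params$seed`.
#' @return a `session_recording`; the ground-truth trace (per-phase or
#'   per-iteration fear, level, rating) is attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_session <- function(params = participant_params(),
                             protocol = c("pretest", "main"),
                             relax_s = 90, fear_s = 90, scene_delay_s = 5,
                             n_iter = 10, exposure_s = 30,
                             levels = 3, meta = list(), seed = NULL) {
  stopifnot(inherits(params, "participant_params"))
  protocol <- match.arg(protocol)
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  fs <- 500
  if (protocol == "pretest") {
    fear_max <- stats::plogis(params$sensitivity *
                                (5 - params$level_midpoint))
    segs <- list(list(dur = relax_s, fear = 0, level = 1),
                 list(dur = scene_delay_s, fear = fear_max / 2, level = 5),
                 list(dur = fear_s, fear = fear_max, level = 5))
    markers <- marker_stream(c(relax_s, relax_s + scene_delay_s),
                             c("Spider_Scene", "Spider_Stimulus"))
    truth <- data.frame(phase = c("relax", "transition", "fear"),
                        fear = vapply(segs, `[[`, 0, "fear"),
                        level = vapply(segs, `[[`, 0, "level"),
                        onset_s = c(0, relax_s, relax_s + scene_delay_s))
  } else {
    levels <- rep_len(levels, n_iter)
    state <- NULL
    segs <- vector("list", n_iter)
    truth <- data.frame(iteration = seq_len(n_iter), level = levels,
                        fear = NA_real_, rating = NA_integer_,
                        onset_s = (seq_len(n_iter) - 1) * exposure_s)
    for (i in seq_len(n_iter)) {
      state <- update_fear_state(state, levels[i], params)
      segs[[i]] <- list(dur = exposure_s, fear = state$value,
                        level = levels[i])
      truth$fear[i] <- state$value
      truth$rating[i] <- .quantize_rating(state$value)
    }
    chg <- c(TRUE, diff(levels) != 0)
    markers <- marker_stream(truth$onset_s[chg],
                             rep("Level_Change", sum(chg)))
  }
  eeg_parts <- lapply(segs, function(s)
    simulate_eeg(s$fear, params, s$dur, fs = fs)$samples)
  eeg <- eeg_block(do.call(cbind, eeg_parts), montage_labels(), fs)
  hr_parts <- list(times = numeric(), values = numeric())
  off <- 0
  for (s in segs) {
    h <- simulate_hr(s$fear, params, s$dur, level = s$level, t0 = off)
    hr_parts$times <- c(hr_parts$times, h$times)
    hr_parts$values <- c(hr_parts$values, h$values)
    off <- off + s$dur
  }
  hr <- hr_series(hr_parts$times, hr_parts$values)
  session <- session_recording(eeg, hr, markers, meta = meta)
  attr(session, "ground_truth") <- truth
  attr(session, "declared_duration_s") <- sum(vapply(segs, `[[`, 0, "dur"))
  session
}

#' Create a virtual participant for closed-loop runs
#'
#' Carries the parameters and latent fear state across loop iterations;
#' [run_adaptive_loop()] pulls one exposure window per iteration via
#' [participant_window()] and feeds the controller's level back in.
#'
#' @param params a `participant_params`.
#' @param seed per-participant seed (derives one sub-seed per iteration);
#'   default 1.
#' @return a `virtual_participant`.
#' @export
virtual_participant <- function(params = participant_params(), seed = 1L) {
  structure(list(params = params, state = NULL, seed = as.integer(seed)),
            class = "virtual_participant")
}

#' Generate one exposure window from a virtual participant
#'
#' Advances the latent fear state under the commanded level, simulates
#' `exposure_s` of EEG and HR, and reports the quantized rating.
#'
#' @param vp a `virtual_participant`.
#' @param level commanded stimulus level, 1..5.
#' @param exposure_s window length; default 30 s.
#' @return list with `participant` (advanced copy), `window`
#'   (`session_recording`), `rating`, `fear`.
#' @export
participant_window <- function(vp, level, exposure_s = 30) {
  stopifnot(inherits(vp, "virtual_participant"))
  iter <- if (is.null(vp$state)) 0L else vp$state$iteration
  sub_seed <- (vp$seed + 7919L * (iter + 1L)) %% .Machine$integer.max
  set.seed(sub_seed)
  vp$state <- update_fear_state(vp$state, level, vp$params)
  eeg <- simulate_eeg(vp$state$value, vp$params, exposure_s)
  hr <- simulate_hr(vp$state$value, vp$params, exposure_s, level = level)
  win <- session_recording(eeg, hr, marker_stream())
  list(participant = vp, window = win,
       rating = .quantize_rating(vp$state$value), fear = vp$state$value)
}
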