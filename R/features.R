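#' Spectral and heart-rate feature layer
#'
#' Shared feature extraction for calibration, online control, and offline
#' analysis: fixed-length windowing, Welch power spectra (Hann taper, 50%
#' overlap), trapezoidal band powers, the frontal alpha asymmetry index
#' FAA = ln(right alpha power) - ln(left alpha power), and heart-rate
#' features derived from the 5-s PPG-based series.
#'
#' @name features
NULL

#' Frequency band definition
#'
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz, `0 <= low < high`. Powers are
#'   integrated over `[low, high)`.
#' @return a `band_definition`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Default topographic/offline band set
#'
#' Delta 0-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz. Gamma is
#' retained as labeled even though the 40 Hz low-pass truncates content
#' above 40 Hz. The FAA alpha band is wider (8-13 Hz, see
#' [faa_alpha_band()]) by convention.
#'
#' @return named list of `band_definition`s in canonical order.
#' @export
default_bands <- function() {
  list(delta = band_definition("delta", 0, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 12),
       beta  = band_definition("beta", 12, 30),
       gamma = band_definition("gamma", 30, 45))
}

#' Alpha band used for the FAA index (8-13 Hz)
#' @export
faa_alpha_band <- function() band_definition("alpha_faa", 8, 13)

#' Segment an EEG block into fixed-length windows
#'
#' Floor partition: window starts advance by `window_s * (1 - overlap)`
#' and any trailing partial window is discarded, giving
#' `floor((T - w) / (w * (1 - o))) + 1` epochs.
#'
#' @param eeg an `eeg_block`.
#' @param window_s window length in seconds.
#' @param overlap_fraction fractional overlap in `[0, 1)`; default 0
#'   (non-overlapping).
#' @return an `epoch_set`: list with `epochs` (array channels x samples x
#'   n), `onsets_s`, `fs_hz`, `channel_labels`, `window_s`.
#' @export
segment_windows <- function(eeg, window_s, overlap_fraction = 0) {
  stopifnot(inherits(eeg, "eeg_block"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  n <- ncol(eeg$samples)
  wn <- as.integer(round(window_s * eeg$fs_hz))
  if (wn > n) stop("window too long: ", window_s, " s exceeds the block")
  step <- max(1L, as.integer(round(wn * (1 - overlap_fraction))))
  starts <- seq.int(0L, n - wn, by = step)
  epochs <- array(0, dim = c(nrow(eeg$samples), wn, length(starts)),
                  dimnames = list(eeg$channel_labels, NULL, NULL))
  for (k in seq_along(starts))
    epochs[, , k] <- eeg$samples[, (starts[k] + 1L):(starts[k] + wn)]
  structure(list(epochs = epochs,
                 onsets_s = eeg$t0 + starts / eeg$fs_hz,
                 fs_hz = eeg$fs_hz,
                 channel_labels = eeg$channel_labels,
                 window_s = wn / eeg$fs_hz),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s, %d channels @ %g Hz\n",
              n_epochs(x), x$window_s, dim(x$epochs)[1], x$fs_hz))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x an `epoch_set`.
#' @export
n_epochs <- function(x) dim(x$epochs)[3]

#' Welch power spectral density
#'
#' Mean of Hann-tapered, mean-removed, 50%-overlapping segment
#' periodograms, one-sided density scaling (uV^2/Hz): integrating the
#' spectrum of a unit-amplitude sinusoid returns ~0.5 uV^2.
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param fs sampling rate in Hz.
#' @param seg_len_s Welch segment length in seconds. Default `NULL` uses
#'   `min(2, duration)`: 30-s epochs get 2-s segments (0.5 Hz resolution),
#'   500-ms calibration windows a single full-length segment (2 Hz).
#' @param overlap_fraction segment overlap; default 0.5.
#' @return a `psd` object: list with `freq` (Hz) and `power`
#'   (channels x frequencies matrix).
#' @export
welch_psd <- function(x, fs, seg_len_s = NULL, overlap_fraction = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (is.null(seg_len_s)) seg_len_s <- min(2, n / fs)
  nper <- as.integer(round(seg_len_s * fs))
  if (nper < 2L || nper > n)
    stop("segment too short: need at least one full taper length of data")
  step <- max(1L, as.integer(round(nper * (1 - overlap_fraction))))
  starts <- seq.int(0L, n - nper, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, nper - 1L) / nper)  # periodic Hann
  u <- sum(win^2)
  nf <- nper %/% 2L + 1L
  acc <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, (s + 1L):(s + nper), drop = FALSE]
    seg <- sweep(seg, 1L, rowMeans(seg))
    seg <- sweep(seg, 2L, win, `*`)
    ft <- t(apply(seg, 1L, stats::fft))
    if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
    p <- Mod(ft[, seq_len(nf), drop = FALSE])^2 / (fs * u)
    p[, -c(1L, if (nper %% 2L == 0L) nf)] <-
      2 * p[, -c(1L, if (nper %% 2L == 0L) nf)]
    acc <- acc + p
  }
  structure(list(freq = seq.int(0L, nf - 1L) * fs / nper,
                 power = acc / length(starts)),
            class = "psd")
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over grid frequencies in
#' `[low_hz, high_hz)`; a band covering a single grid point falls back to
#' point value times grid spacing.
#'
#' @param spectrum a `psd` object.
#' @param band a `band_definition`.
#' @return numeric vector of band powers (uV^2), one per channel.
#' @export
bandpower <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "psd"), inherits(band, "band_definition"))
  idx <- which(spectrum$freq >= band$low_hz & spectrum$freq < band$high_hz)
  if (!length(idx)) stop("band outside spectrum: ", band$name)
  if (length(idx) == 1L) {
    df <- if (length(spectrum$freq) > 1L) diff(spectrum$freq[1:2]) else 1
    return(spectrum$power[, idx] * df)
  }
  apply(spectrum$power[, idx, drop = FALSE], 1L,
        function(p) pracma::trapz(spectrum$freq[idx], p))
}

#' Frontal alpha asymmetry index
#'
#' `FAA = ln(right) - ln(left)` on alpha powers of a homologous electrode
#' pair. Negative values indicate relatively greater right-hemisphere
#' activation (alpha power is inversely related to activation), the
#' direction expected under fear.
#'
#' @param left_alpha_power,right_alpha_power alpha-band powers (uV^2),
#'   strictly positive; vectorized.
#' @return dimensionless index, `log(right / left)`.
#' @export
faa_index <- function(left_alpha_power, right_alpha_power) {
  if (any(left_alpha_power <= 0) || any(right_alpha_power <= 0))
    stop("invalid power: alpha powers must be strictly positive")
  log(right_alpha_power) - log(left_alpha_power)
}

#' Calibration feature matrix: 4 FAA values + mean HR per epoch
#'
#' For each epoch, alpha power (8-13 Hz) is estimated by Welch's method on
#' the epoch, the FAA index is computed for each electrode pair, and the
#' mean of the EEG-aligned heart-rate series over the epoch window is
#' appended, giving the 5-feature calibration vector.
#'
#' @param epochs an `epoch_set` (e.g. 500-ms calibration windows).
#' @param hr an `hr_series` overlapping the epochs.
#' @param pairs FAA pair table, see [default_faa_pairs()].
#' @param alpha_band `band_definition` for FAA alpha; default 8-13 Hz.
#' @return numeric matrix, epochs x 5, columns `FAA_*` then `mean_HR`.
#' @export
calibration_features <- function(epochs, hr, pairs = default_faa_pairs(),
                                 alpha_band = faa_alpha_band()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(hr, "hr_series"))
  need <- c(pairs$left, pairs$right)
  if (!all(need %in% epochs$channel_labels))
    stop("montage mismatch: missing pair channels ",
         paste(setdiff(need, epochs$channel_labels), collapse = ", "))
  if (!length(hr$times)) stop("no HR data available")
  n <- n_epochs(epochs)
  out <- matrix(NA_real_, n, nrow(pairs) + 1L,
                dimnames = list(NULL, c(pairs$name, "mean_HR")))
  for (k in seq_len(n)) {
    seg <- epochs$epochs[need, , k, drop = FALSE][, , 1]
    spec <- welch_psd(seg, epochs$fs_hz,
                      seg_len_s = ncol(seg) / epochs$fs_hz)
    ap <- bandpower(spec, alpha_band)
    names(ap) <- need
    out[k, seq_len(nrow(pairs))] <-
      faa_index(ap[pairs$left], ap[pairs$right])
    t0 <- epochs$onsets_s[k]
    tt <- t0 + (seq_len(ncol(seg)) - 1L) / epochs$fs_hz
    out[k, "mean_HR"] <- if (length(hr$times) == 1L) hr$values else
      mean(stats::approx(hr$times, hr$values, xout = tt, rule = 2)$y)
  }
  out
}

#' Offline feature matrix: 160 band powers + 4 FAA values per epoch
#'
#' Per 32-channel epoch, Welch band power is computed for every channel in
#' each of the five canonical bands (channel-major ordering: all bands of
#' channel 1, then channel 2, ...), followed by the four FAA indices
#' (8-13 Hz alpha), for 164 features in a fixed, serialized order. Columns
#' are named `<channel>_<band>` and `FAA_<pair>`.
#'
#' @param epochs an `epoch_set` of 30-s, 32-channel epochs.
#' @param bands band set; default [default_bands()].
#' @param pairs FAA pair table.
#' @param faa_band FAA alpha band; default 8-13 Hz.
#' @return numeric matrix, epochs x 164.
#' @export
offline_features <- function(epochs, bands = default_bands(),
                             pairs = default_faa_pairs(),
                             faa_band = faa_alpha_band()) {
  stopifnot(inherits(epochs, "epoch_set"))
  labels <- epochs$channel_labels
  if (length(labels) != 32L)
    stop("montage mismatch: offline features require the 32-channel montage")
  need <- c(pairs$left, pairs$right)
  if (!all(need %in% labels))
    stop("montage mismatch: missing pair channels")
  bp_names <- as.vector(vapply(labels, function(ch)
    paste0(ch, "_", vapply(bands, `[[`, "", "name")), character(length(bands))))
  cn <- c(bp_names, pairs$name)
  n <- n_epochs(epochs)
  out <- matrix(NA_real_, n, length(cn), dimnames = list(NULL, cn))
  for (k in seq_len(n)) {
    spec <- welch_psd(epochs$epochs[, , k], epochs$fs_hz)
    bp <- vapply(bands, function(b) bandpower(spec, b), numeric(length(labels)))
    rownames(bp) <- labels
    out[k, seq_along(bp_names)] <- as.vector(t(bp))  # channel-major
    ap <- bandpower(spec, faa_band)
    names(ap) <- labels
    if (any(ap[need] <= 0))
      stop("invalid power: zero alpha power in a pair channel; reject this epoch")
    out[k, pairs$name] <- faa_index(ap[pairs$left], ap[pairs$right])
  }
  out
}

#' Estimate heart rate from a raw PPG waveform
#'
#' Systolic peaks are detected with an amplitude-prominence criterion and
#' a refractory minimum peak distance; the heart rate for each 5-s block
#' is `60 / mean(inter-peak interval)` over intervals inside the block.
#' Blocks with fewer than 2 peaks inherit the previous block's value and
#' are flagged.
#'
#' @param ppg numeric PPG waveform.
#' @param fs PPG sampling rate in Hz.
#' @param report_interval_s reporting cadence in seconds; default 5.
#' @return an `hr_series` (times at block centers) with attribute
#'   `"flagged"`, a logical vector marking imputed blocks.
#' @export
estimate_hr_from_ppg <- function(ppg, fs, report_interval_s = 5) {
  if (length(ppg) / fs < 10) stop("need at least 10 s of PPG")
  rng <- range(ppg)
  thr <- rng[1] + 0.5 * diff(rng)
  pk <- if (diff(rng) > 0)
    pracma::findpeaks(ppg, minpeakheight = thr,
                      minpeakdistance = as.integer(round(0.25 * fs)),
                      peakpat = "[+]{1,}[0]{0,}[-]{1,}")  # tolerate plateaus
  else NULL
  pk_t <- if (!is.null(pk)) sort(pk[, 2]) / fs else numeric()
  n_blk <- floor(length(ppg) / fs / report_interval_s)
  times <- (seq_len(n_blk) - 0.5) * report_interval_s
  values <- numeric(n_blk)
  flagged <- logical(n_blk)
  prev <- NA_real_
  for (b in seq_len(n_blk)) {
    lo <- (b - 1) * report_interval_s; hi <- b * report_interval_s
    in_blk <- pk_t[pk_t >= lo & pk_t < hi]
    if (length(in_blk) >= 2L) {
      prev <- values[b] <- 60 / mean(diff(in_blk))
    } else {
      flagged[b] <- TRUE
      values[b] <- prev
    }
  }
  if (all(flagged)) stop("no usable pulse peaks detected in any block")
  if (is.na(values[1L])) {  # leading flagged blocks inherit first estimate
    first <- which(!flagged)[1L]
    values[seq_len(first - 1L)] <- values[first]
  }
  out <- hr_series(times, values, native_interval_s = report_interval_s)
  attr(out, "flagged") <- flagged
  out
}

#' Upsample a heart-rate series onto the EEG time grid
#'
#' Linear interpolation at every EEG sample time; beyond the HR support
#' the endpoint values are held constant.
#'
#' @param hr an `hr_series` (non-empty).
#' @param eeg an `eeg_block` with overlapping time range.
#' @return numeric vector of bpm values, one per EEG sample.
#' @export
align_hr_to_eeg <- function(hr, eeg) {
  stopifnot(inherits(hr, "hr_series"), inherits(eeg, "eeg_block"))
  if (!length(hr$times)) stop("empty HR series")
  if (length(hr$times) == 1L)
    return(rep(hr$values, ncol(eeg$samples)))
  stats::approx(hr$times, hr$values, xout = eeg_times(eeg), rule = 2)$y
}
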