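#' EEG preprocessing chain
#'
#' The cleaning chain applied to every recording, in order: zero-phase
#' Butterworth bandpass, common-average re-reference, pre-marker baseline
#' correction. Bad channels are scored by a robust deviation criterion and
#' replaced by inverse-distance interpolation over the montage sphere.
#'
#' @name preprocess
NULL

#' Bandpass filter specification
#'
#' @param low_hz high-pass cutoff (Hz); default 1.
#' @param high_hz low-pass cutoff (Hz); default 40.
#' @param order Butterworth order; default 4.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 40, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

#' Zero-phase Butterworth bandpass
#'
#' Applies an order-`spec$order` Butterworth bandpass forward and backward
#' (`signal::filtfilt`), so the output has no group delay and the effective
#' magnitude response is the squared single-pass response. Passband gain is
#' ~1; the default (1, 40) Hz design attenuates 50 Hz mains by ~18 dB.
#'
#' @param eeg an `eeg_block`.
#' @param spec a `filter_spec`; cutoffs must be below Nyquist.
#' @return filtered `eeg_block`, same shape and labels.
#' @export
bandpass_filter <- function(eeg, spec = filter_spec()) {
  stopifnot(inherits(eeg, "eeg_block"), inherits(spec, "filter_spec"))
  nyq <- eeg$fs_hz / 2
  if (spec$high_hz >= nyq)
    stop("invalid filter: high cutoff (", spec$high_hz,
         " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  out <- t(apply(eeg$samples, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_block(out, eeg$channel_labels, eeg$fs_hz, eeg$t0)
}

#' Common average reference
#'
#' Subtracts, at every time sample, the mean across all channels from each
#' channel; afterwards the instantaneous channel mean is 0. Idempotent.
#'
#' @param eeg an `eeg_block` with at least 2 channels.
#' @return re-referenced `eeg_block`.
#' @export
common_average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_block"))
  if (nrow(eeg$samples) < 2L) stop("CAR undefined for a single channel")
  avg <- colMeans(eeg$samples)
  eeg_block(sweep(eeg$samples, 2L, avg), eeg$channel_labels, eeg$fs_hz, eeg$t0)
}

#' Baseline correction from the pre-marker interval
#'
#' Uses the `baseline_s` seconds immediately preceding the first marker as
#' the baseline window; each channel's mean over that window is subtracted
#' from the entire signal.
#'
#' @param eeg an `eeg_block`.
#' @param markers a `marker_stream` with at least one event no earlier than
#'   `baseline_s` after the block start.
#' @param baseline_s baseline window length in seconds; default 5.
#' @return baseline-corrected `eeg_block`.
#' @export
baseline_correct <- function(eeg, markers, baseline_s = 5) {
  stopifnot(inherits(eeg, "eeg_block"), inherits(markers, "marker_stream"))
  if (!n_markers(markers)) stop("insufficient baseline: no markers")
  t1 <- min(markers$events$time_s)
  t0 <- t1 - baseline_s
  if (t0 < eeg$t0 - 1e-9)
    stop("insufficient baseline: first marker earlier than ", baseline_s,
         " s after signal start")
  fs <- eeg$fs_hz
  i0 <- as.integer(round((t0 - eeg$t0) * fs)) + 1L
  i1 <- as.integer(round((t1 - eeg$t0) * fs))
  base <- rowMeans(eeg$samples[, i0:i1, drop = FALSE])
  eeg_block(sweep(eeg$samples, 1L, base), eeg$channel_labels, eeg$fs_hz, eeg$t0)
}

#' Detect bad channels by robust amplitude deviation
#'
#' Each channel's robust amplitude (1.4826 * MAD of its samples) is compared
#' to the median amplitude across channels; the deviation score is
#' `|amp - median| / (scaled MAD across channels)`. Channels scoring above
#' `z_threshold` are flagged. Scores are invariant to a common positive
#' rescaling of all channels.
#'
#' @param eeg an `eeg_block` with at least 4 channels.
#' @param z_threshold robust-z cutoff; default 5.
#' @return a `channel_qc_report`: list with `deviation_score` (named),
#'   `bad_labels`, `threshold`.
#' @export
detect_bad_channels <- function(eeg, z_threshold = 5) {
  stopifnot(inherits(eeg, "eeg_block"))
  if (nrow(eeg$samples) < 4L) stop("need at least 4 channels")
  amp <- apply(eeg$samples, 1L, stats::mad)   # mad() is already scaled
  ctr <- stats::median(amp)
  disp <- stats::mad(amp)
  if (disp == 0) {
    warning("zero amplitude dispersion across channels; no channels flagged")
    scores <- stats::setNames(rep(0, length(amp)), eeg$channel_labels)
  } else {
    scores <- stats::setNames(abs(amp - ctr) / disp, eeg$channel_labels)
  }
  structure(list(deviation_score = scores,
                 bad_labels = names(scores)[scores > z_threshold],
                 threshold = z_threshold),
            class = "channel_qc_report")
}

#' @export
print.channel_qc_report <- function(x, ...) {
  cat(sprintf("<channel_qc_report> threshold %.1f, %d bad channel(s)%s\n",
              x$threshold, length(x$bad_labels),
              if (length(x$bad_labels))
                paste0(": ", paste(x$bad_labels, collapse = ", ")) else ""))
  invisible(x)
}

#' Interpolate bad channels by inverse-distance weighting
#'
#' Each flagged channel is replaced by a weighted combination of all good
#' channels, with weights proportional to `1 / d^2` for Euclidean distance
#' `d` on the unit-sphere montage, normalized to sum to 1. Good channels
#' are untouched.
#'
#' @param eeg an `eeg_block`.
#' @param bad character vector of channel labels to rebuild (a strict
#'   subset of the channels).
#' @param positions montage data.frame (`label`, `x`, `y`, `z`); defaults to
#'   the packaged 32-channel 10-20 table.
#' @param power inverse-distance exponent; default 2.
#' @return `eeg_block` with flagged channels reconstructed.
#' @export
interpolate_channels <- function(eeg, bad, positions = montage_1020(),
                                 power = 2) {
  stopifnot(inherits(eeg, "eeg_block"))
  if (!length(bad)) return(eeg)
  if (!all(bad %in% eeg$channel_labels))
    stop("bad labels not present in the block: ",
         paste(setdiff(bad, eeg$channel_labels), collapse = ", "))
  good <- setdiff(eeg$channel_labels, bad)
  if (!length(good)) stop("cannot interpolate: all channels bad")
  if (!all(eeg$channel_labels %in% positions$label))
    stop("positions missing for channels: ",
         paste(setdiff(eeg$channel_labels, positions$label), collapse = ", "))
  pos <- as.matrix(positions[match(eeg$channel_labels, positions$label),
                             c("x", "y", "z")])
  rownames(pos) <- eeg$channel_labels
  out <- eeg$samples
  for (ch in bad) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[ch, ])^2))
    w <- 1 / pmax(d, 1e-9)^power
    w <- w / sum(w)
    out[ch, ] <- as.vector(w %*% eeg$samples[good, , drop = FALSE])
  }
  eeg_block(out, eeg$channel_labels, eeg$fs_hz, eeg$t0)
}

#' Run the standard preprocessing chain on a session
#'
#' Filter -> common average reference -> (optional) baseline correction
#' from the pre-marker window -> (optional) bad-channel detection and
#' interpolation. Baseline correction is skipped automatically for
#' marker-free excerpts such as online 30-s control windows, where the
#' 1 Hz high-pass already removes the DC component.
#'
#' @param session a `session_recording`.
#' @param spec a `filter_spec`.
#' @param baseline_s baseline window (s); `NULL` or a marker-free session
#'   skips baseline correction.
#' @param interpolate_bad if `TRUE`, detect and rebuild bad channels.
#' @param z_threshold robust-z cutoff for bad-channel detection.
#' @return the session with a cleaned EEG block; QC report (if run) is
#'   attached as attribute `"qc"`.
#' @export
preprocess_session <- function(session, spec = filter_spec(),
                               baseline_s = 5, interpolate_bad = FALSE,
                               z_threshold = 5) {
  stopifnot(inherits(session, "session_recording"))
  eeg <- bandpass_filter(session$eeg, spec)
  eeg <- common_average_reference(eeg)
  if (!is.null(baseline_s) && n_markers(session$markers) &&
      min(session$markers$events$time_s) >= baseline_s)
    eeg <- baseline_correct(eeg, session$markers, baseline_s)
  qc <- NULL
  if (interpolate_bad) {
    qc <- detect_bad_channels(eeg, z_threshold)
    if (length(qc$bad_labels))
      eeg <- interpolate_channels(eeg, qc$bad_labels)
  }
  session$eeg <- eeg
  if (!is.null(qc)) attr(session, "qc") <- qc
  session
}
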