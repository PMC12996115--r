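#' Synchronized EEG/HR/marker session containers and on-disk format
#'
#' A session bundles one participant run: a multichannel EEG block, a
#' low-rate heart-rate series, an event-marker stream, and participant
#' metadata (questionnaire scores). All streams share one clock whose
#' origin is the first EEG sample (t = 0); constructors normalize times
#' on creation so downstream code never sees raw acquisition clocks.
#'
#' @name session-io
NULL

#' Construct an EEG block
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param channel_labels character vector of 10-20 electrode names, one per
#'   row of `samples`. Label order is authoritative everywhere downstream.
#' @param fs_hz sampling rate in Hz (500 for the supported amplifier setup).
#' @param t0 time of the first sample in seconds (0 after normalization).
#' @return an object of class `eeg_block`.
#' @export
eeg_block <- function(samples, channel_labels, fs_hz, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length (", length(channel_labels),
         ") must equal the sample matrix row count (", nrow(samples), ")")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("EEG samples must all be finite")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, channel_labels = as.character(channel_labels),
         fs_hz = fs_hz, t0 = t0),
    class = "eeg_block")
}

#' @export
print.eeg_block <- function(x, ...) {
  cat(sprintf("<eeg_block> %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz, x$t0))
  invisible(x)
}

#' Duration of an EEG block in seconds
#' @param eeg an `eeg_block`.
#' @export
eeg_duration <- function(eeg) ncol(eeg$samples) / eeg$fs_hz

#' Sample times of an EEG block
#' @param eeg an `eeg_block`.
#' @return numeric vector, seconds; `t0` + (0:(n-1))/fs.
#' @export
eeg_times <- function(eeg) eeg$t0 + (seq_len(ncol(eeg$samples)) - 1L) / eeg$fs_hz

#' Construct a heart-rate series
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values heart rate in beats per minute; must lie in (20, 250).
#' @param native_interval_s native reporting cadence in seconds (5 s for the
#'   headset PPG sensor).
#' @return an object of class `hr_series`.
#' @export
hr_series <- function(times, values, native_interval_s = 5) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop("HR times must be strictly increasing")
  if (length(values) && (any(!is.finite(values)) ||
                         any(values <= 20 | values >= 250)))
    stop("HR values must be finite and within (20, 250) bpm")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 native_interval_s = native_interval_s),
            class = "hr_series")
}

#' Construct a marker stream
#'
#' @param times event times in seconds, non-decreasing.
#' @param labels non-empty event labels (`Spider_Scene`, `Spider_Stimulus`,
#'   `Level_Change`, `Beep`, `Rating`, or free text).
#' @return an object of class `marker_stream`.
#' @export
marker_stream <- function(times = numeric(), labels = character()) {
  if (length(times) != length(labels))
    stop("times and labels must have equal length")
  if (length(times) > 1L && any(diff(times) < 0))
    stop("marker times must be non-decreasing")
  if (length(labels) && any(!nzchar(labels)))
    stop("marker labels must be non-empty")
  structure(list(events = data.frame(time_s = as.numeric(times),
                                     label = as.character(labels),
                                     stringsAsFactors = FALSE)),
            class = "marker_stream")
}

#' Number of events in a marker stream
#' @param x a `marker_stream`.
#' @export
n_markers <- function(x) nrow(x$events)

#' Look up the first marker with a given label
#' @param markers a `marker_stream`.
#' @param label label to search for.
#' @return time in seconds, or `NA` if absent.
#' @export
marker_time <- function(markers, label) {
  hit <- markers$events$time_s[markers$events$label == label]
  if (length(hit)) hit[1L] else NA_real_
}

# Questionnaire score ranges enforced on session metadata.
.score_ranges <- list(
  stai_s = c(20, 80), stai_t = c(20, 80), fsq = c(18, 126),
  bmis = c(-10, 10))

#' Construct a session recording
#'
#' Streams are shifted so the first EEG sample sits at t = 0 and must
#' overlap a common time interval. Recognized metadata scores (`stai_s`,
#' `stai_t`, `fsq`, `bmis`) are validated against instrument ranges
#' (STAI 20-80, FSQ 18-126, BMIS overall -10..10).
#'
#' @param eeg an `eeg_block`.
#' @param hr an `hr_series`.
#' @param markers a `marker_stream`.
#' @param meta named list: `participant_id`, questionnaire scores, condition
#'   tags. Optional.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(eeg, hr, markers = marker_stream(),
                              meta = list()) {
  stopifnot(inherits(eeg, "eeg_block"), inherits(hr, "hr_series"),
            inherits(markers, "marker_stream"))
  shift <- eeg$t0
  if (shift != 0) {
    eeg$t0 <- 0
    hr$times <- hr$times - shift
    markers$events$time_s <- markers$events$time_s - shift
  }
  dur <- eeg_duration(eeg)
  if (length(hr$times) && (max(hr$times) < 0 || min(hr$times) > dur))
    stop("HR stream does not overlap the EEG time interval")
  for (nm in names(meta)) {
    key <- if (startsWith(nm, "bmis")) "bmis" else nm
    rng <- .score_ranges[[key]]
    if (!is.null(rng) && is.numeric(meta[[nm]]) &&
        (meta[[nm]] < rng[1] || meta[[nm]] > rng[2]))
      stop(sprintf("meta score '%s' = %g outside instrument range [%g, %g]",
                   nm, meta[[nm]], rng[1], rng[2]))
  }
  structure(list(eeg = eeg, hr = hr, markers = markers, meta = meta),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %.1f s, %d EEG channels @ %g Hz, %d HR samples, %d markers\n",
              eeg_duration(x$eeg), nrow(x$eeg$samples), x$eeg$fs_hz,
              length(x$hr$times), n_markers(x$markers)))
  invisible(x)
}

#' Duration of a session in seconds (EEG extent)
#' @param session a `session_recording`.
#' @export
session_duration <- function(session) eeg_duration(session$eeg)

.session_files <- function(stem) {
  list(header  = paste0(stem, ".header.yaml"),
       eeg     = paste0(stem, ".eeg.csv"),
       hr      = paste0(stem, ".hr.csv"),
       markers = paste0(stem, ".markers.csv"))
}

#' Write a session to disk (delimited-text dialect)
#'
#' The text dialect is a documented four-file set sharing one stem:
#' `<stem>.header.yaml` (sampling rate, ordered channel labels, metadata),
#' `<stem>.eeg.csv` (`time_s` plus one column per channel, microvolts),
#' `<stem>.hr.csv` (`time_s,bpm`), and `<stem>.markers.csv`
#' (`time_s,label`). Channel order is taken from the header on read, never
#' from CSV column order. Numeric columns round-trip to well under 1e-6 uV.
#'
#' @param session a `session_recording`.
#' @param path file stem (no extension).
#' @param dialect only `"text"` is writable.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, dialect = "text") {
  dialect <- match.arg(dialect, c("text", "xdf"))
  if (dialect == "xdf")
    stop("unsupported dialect: XDF is read-only in principle and no XDF ",
         "backend is available; use dialect = \"text\"")
  stopifnot(inherits(session, "session_recording"))
  f <- .session_files(path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- list(
    format = "faaloop-session/1",
    fs_hz = session$eeg$fs_hz,
    t0 = session$eeg$t0,
    n_samples = ncol(session$eeg$samples),
    channel_labels = as.list(session$eeg$channel_labels),
    hr_native_interval_s = session$hr$native_interval_s,
    meta = session$meta)
  yaml::write_yaml(header, f$header)
  eeg_dt <- data.table::as.data.table(t(session$eeg$samples))
  data.table::setnames(eeg_dt, session$eeg$channel_labels)
  eeg_dt <- cbind(data.table::data.table(time_s = eeg_times(session$eeg)), eeg_dt)
  data.table::fwrite(eeg_dt, f$eeg)
  data.table::fwrite(data.table::data.table(time_s = session$hr$times,
                                            bpm = session$hr$values), f$hr)
  data.table::fwrite(session$markers$events, f$markers)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path file stem of a text-dialect session (see [write_session()]).
#' @param dialect `"text"`; requesting `"xdf"` raises an informative error
#'   since no XDF backend is available in this implementation.
#' @return a validated `session_recording`, time-normalized to t = 0.
#' @export
read_session <- function(path, dialect = "text") {
  dialect <- match.arg(dialect, c("text", "xdf"))
  if (dialect == "xdf")
    stop("unsupported dialect: no XDF backend is available; ",
         "convert the recording to the text dialect")
  f <- .session_files(path)
  if (!file.exists(f$header)) stop("incomplete session: missing header file")
  header <- yaml::read_yaml(f$header)
  for (part in c("eeg", "hr")) {
    if (!file.exists(f[[part]]))
      stop("incomplete session: missing ", part, " stream")
  }
  labels <- unlist(header$channel_labels)
  eeg_dt <- data.table::fread(f$eeg)
  if (!all(labels %in% names(eeg_dt)))
    stop("incomplete session: EEG stream lacks channels named in header")
  tcol <- eeg_dt[["time_s"]]
  if (any(diff(tcol) <= 0)) stop("clock error: EEG timestamps not increasing")
  samples <- t(as.matrix(eeg_dt[, labels, with = FALSE]))
  eeg <- eeg_block(samples, labels, header$fs_hz, t0 = tcol[1L])
  hr_dt <- data.table::fread(f$hr)
  if (nrow(hr_dt) && any(diff(hr_dt$time_s) <= 0))
    stop("clock error: HR timestamps not increasing")
  hr <- hr_series(hr_dt$time_s, hr_dt$bpm,
                  native_interval_s = header$hr_native_interval_s %||% 5)
  mk <- if (file.exists(f$markers)) data.table::fread(
    f$markers, colClasses = c(time_s = "numeric", label = "character"))
  else data.table::data.table(time_s = numeric(), label = character())
  markers <- marker_stream(mk$time_s, mk$label)
  session_recording(eeg, hr, markers, meta = header$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a time slice of a session
#'
#' EEG samples falling in `[start_s, end_s)` are kept (count =
#' `round((end - start) * fs)`), HR samples and markers are restricted to
#' the interval, and all times are re-referenced so the slice starts at 0.
#' Slicing is idempotent and adjacent slices concatenate back to the
#' original sample matrix.
#'
#' @param session a `session_recording`.
#' @param start_s,end_s slice bounds in seconds, `start_s < end_s`.
#' @return a `session_recording` covering the slice.
#' @export
slice_session <- function(session, start_s, end_s) {
  stopifnot(inherits(session, "session_recording"))
  if (!(start_s < end_s)) stop("start_s must be < end_s")
  dur <- session_duration(session)
  if (end_s <= 0 || start_s >= dur)
    stop("out of range: slice does not intersect the session")
  fs <- session$eeg$fs_hz
  i0 <- max(0L, as.integer(round(start_s * fs)))
  i1 <- min(ncol(session$eeg$samples), as.integer(round(end_s * fs)))
  if (i1 <= i0) stop("out of range: empty slice")
  eeg <- eeg_block(session$eeg$samples[, (i0 + 1L):i1, drop = FALSE],
                   session$eeg$channel_labels, fs, t0 = 0)
  off <- i0 / fs
  keep_hr <- session$hr$times >= start_s & session$hr$times < end_s
  hr <- structure(list(times = session$hr$times[keep_hr] - off,
                       values = session$hr$values[keep_hr],
                       native_interval_s = session$hr$native_interval_s),
                  class = "hr_series")
  ev <- session$markers$events
  keep_mk <- ev$time_s >= start_s & ev$time_s < end_s
  markers <- marker_stream(ev$time_s[keep_mk] - off, ev$label[keep_mk])
  session_recording(eeg, hr, markers, meta = session$meta)
}
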