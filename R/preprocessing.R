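#' Remove the DC component of a signal
#'
#' Subtracts the arithmetic mean, so the output has zero mean. Surface EMG
#' channels carry an electrode/amplifier DC offset that is uninformative for
#' movement characterization and would dominate the RMS feature.
#'
#' @param x numeric vector, one channel.
#' @return numeric vector of the same length with zero mean.
#' @export
remove_dc <- function(x) {
  if (length(x) == 0L) stop("signal is empty")
  x - mean(x)
}

#' Affine per-channel calibration
#'
#' `calibrate()` applies `(x - offset) * gain`. `rest_calibration()` derives
#' the affine parameters from a designated rest segment: the offset is the
#' rest mean; with `normalize = TRUE` the gain is the reciprocal of the rest
#' RMS (after centering), so the rest segment itself calibrates to unit RMS.
#' The default gain is 1 (offset correction only).
#'
#' @param x numeric vector, one channel.
#' @param gain scale factor, must be non-zero.
#' @param offset amplitude offset subtracted before scaling.
#' @return `calibrate`: the calibrated signal. `rest_calibration`: a list with
#'   elements `gain` and `offset`.
#' @export
calibrate <- function(x, gain = 1, offset = 0) {
  if (!is.numeric(gain) || length(gain) != 1L || gain == 0)
    stop("gain must be a single non-zero number")
  (x - offset) * gain
}

#' @param rest numeric vector, the rest segment of the same channel.
#' @param normalize if TRUE, gain = 1 / RMS(rest - mean(rest)); if FALSE
#'   (default) gain = 1.
#' @rdname calibrate
#' @export
rest_calibration <- function(rest, normalize = FALSE) {
  if (length(rest) == 0L) stop("rest segment is empty")
  offset <- mean(rest)
  gain <- 1
  if (normalize) {
    r <- rms(rest - offset)
    if (r == 0) stop("rest segment has zero RMS after centering; cannot normalize")
    gain <- 1 / r
  }
  list(gain = gain, offset = offset)
}

#' Band-pass filter an sEMG channel
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward-backward with
#' [signal::filtfilt()] so window boundaries are not skewed by filter delay).
#' The default 20-450 Hz band retains the surface-EMG energy band (the
#' dominant frequencies lie around 70-300 Hz) while rejecting motion artifact
#' below 20 Hz and keeping the upper edge below the 500 Hz Nyquist limit of
#' 1 kHz sampling.
#'
#' @param x numeric vector, one channel.
#' @param sample_rate sampling rate in Hz.
#' @param low_hz lower cutoff (Hz), default 20.
#' @param high_hz upper cutoff (Hz), default 450.
#' @return filtered signal, same length.
#' @export
bandpass <- function(x, sample_rate, low_hz = 20, high_hz = 450) {
  if (length(x) == 0L) stop("signal is empty")
  nyq <- sample_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("cutoffs must satisfy 0 < low_hz < high_hz < sample_rate/2")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Notch filter for power-line interference
#'
#' Zero-phase Butterworth band-stop centered on the mains frequency (60 Hz by
#' default), with stop-band width `f0_hz / q`. Removes power-line pickup
#' without disturbing the neighbouring EMG band (attenuation at 100 Hz is
#' negligible at the default quality factor).
#'
#' @param x numeric vector, one channel.
#' @param sample_rate sampling rate in Hz.
#' @param f0_hz notch center frequency (Hz), default 60.
#' @param q quality factor: stop-band width is `f0_hz / q` Hz. Default 30
#'   (2 Hz wide at 60 Hz).
#' @return filtered signal, same length.
#' @export
notch <- function(x, sample_rate, f0_hz = 60, q = 30) {
  if (length(x) == 0L) stop("signal is empty")
  nyq <- sample_rate / 2
  if (!(f0_hz > 0 && f0_hz < nyq))
    stop("f0_hz must lie strictly between 0 and sample_rate/2")
  if (!(q > 0)) stop("q must be positive")
  bw <- f0_hz / q
  edges <- c(f0_hz - bw / 2, f0_hz + bw / 2) / nyq
  bf <- signal::butter(2, edges, type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

#' Root-mean-square amplitude
#'
#' The single feature the classifier consumes per channel and movement window:
#' `sqrt(mean(x^2))`.
#'
#' @param x numeric vector (non-empty).
#' @return non-negative scalar.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("segment is empty")
  sqrt(mean(x^2))
}

#' Cue-aligned movement windows
#'
#' Converts a cue schedule into one analysis window per cued movement. Each
#' animation lasts 8.3 s: 0.4 s initial rest, 2.9 s forward movement, 1.25 s
#' hold, 2.9 s backward movement, 0.8 s final rest. The default window spans
#' the active portion, from cue + 0.4 s to cue + 7.5 s (excluding the final
#' rest), clipped to the recording; cues falling outside the recording are
#' skipped with a warning.
#'
#' @param rec a [recording()].
#' @param cues data.frame with columns `onset_s`, `movement_label`.
#' @param start_offset seconds after the cue at which the window starts
#'   (default 0.4).
#' @param end_offset seconds after the cue at which the window ends
#'   (default 7.5 = 0.4 + 2.9 + 1.25 + 2.9).
#' @return data.frame with columns `start`, `end` (seconds) and `label`.
#' @export
extract_windows <- function(rec, cues, start_offset = 0.4, end_offset = 7.5) {
  stopifnot(inherits(rec, "recording"))
  stopifnot(end_offset > start_offset)
  dur <- recording_duration(rec)
  out <- list()
  for (i in seq_len(nrow(cues))) {
    onset <- cues$onset_s[i]
    start <- onset + start_offset
    end <- onset + end_offset
    if (onset < 0 || start >= dur) {
      warning(sprintf("cue %d (%s) at t=%.3f s lies outside the recording; skipped",
                      i, cues$movement_label[i], onset))
      next
    }
    if (end > dur) {
      warning(sprintf("window for cue %d (%s) clipped to recording end (%.3f s)",
                      i, cues$movement_label[i], dur))
      end <- dur
    }
    out[[length(out) + 1L]] <- data.frame(
      start = start, end = end, label = cues$movement_label[i],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Energy-based onset window detector
#'
#' Optional alternative to fixed cue-aligned windows: finds the contiguous
#' region where the moving RMS exceeds `k` times the rest-level RMS.
#'
#' @param x numeric vector, one (preprocessed) channel.
#' @param sample_rate sampling rate in Hz.
#' @param rest_rms rest-level RMS of the same channel.
#' @param k activity threshold multiplier (default 3).
#' @param win_s moving-RMS window length in seconds (default 0.1).
#' @return data.frame with `start`, `end` in seconds (0 rows if no activity).
#' @export
detect_active_window <- function(x, sample_rate, rest_rms, k = 3, win_s = 0.1) {
  if (length(x) == 0L) stop("signal is empty")
  w <- max(1L, round(win_s * sample_rate))
  mov <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  active <- which(!is.na(mov) & mov > k * rest_rms)
  if (!length(active))
    return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = (min(active) - 1L) / sample_rate,
             end = max(active) / sample_rate)
}

#' Preprocessing configuration
#'
#' @param low_hz,high_hz band-pass cutoffs in Hz.
#' @param notch_hz,notch_q notch center frequency and quality factor.
#' @param calibration `NULL` (none), or a list of per-channel
#'   `list(gain, offset)` entries named by channel id.
#' @param channels optional character vector of channel ids to use (subset
#'   selection); `NULL` keeps all channels.
#' @param start_offset,end_offset window placement relative to each cue, in
#'   seconds.
#' @return a list of class `preproc_config`.
#' @export
preproc_config <- function(low_hz = 20, high_hz = 450, notch_hz = 60,
                           notch_q = 30, calibration = NULL, channels = NULL,
                           start_offset = 0.4, end_offset = 7.5) {
  structure(list(low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz,
                 notch_q = notch_q, calibration = calibration,
                 channels = channels, start_offset = start_offset,
                 end_offset = end_offset),
            class = "preproc_config")
}

#' Turn a recording into per-movement RMS feature vectors
#'
#' Runs the full preprocessing chain per channel — calibration, DC removal,
#' band-pass, notch — then windows the signal around each cue and computes the
#' per-channel RMS of each window. The result is the classifier input: one
#' feature vector (one RMS value per channel) per cued movement, carrying the
#' cue's label.
#'
#' @param rec a [recording()].
#' @param cues cue schedule data.frame (`onset_s`, `movement_label`).
#' @param config a [preproc_config()].
#' @return data.frame with one row per window: a `label` column plus one RMS
#'   column per channel (named by channel id).
#' @export
featurize <- function(rec, cues, config = preproc_config()) {
  stopifnot(inherits(rec, "recording"))
  if (!is.null(config$channels)) rec <- select_channels(rec, config$channels)
  sr <- rec$sample_rate
  filtered <- rec$samples
  for (ch in rec$channel_ids) {
    x <- filtered[, ch]
    if (!is.null(config$calibration)) {
      cal <- config$calibration[[ch]]
      if (!is.null(cal)) x <- calibrate(x, cal$gain, cal$offset)
    }
    x <- remove_dc(x)
    x <- bandpass(x, sr, config$low_hz, config$high_hz)
    x <- notch(x, sr, config$notch_hz, config$notch_q)
    filtered[, ch] <- x
  }
  windows <- extract_windows(rec, cues, config$start_offset, config$end_offset)
  feats <- matrix(0, nrow(windows), length(rec$channel_ids),
                  dimnames = list(NULL, rec$channel_ids))
  for (i in seq_len(nrow(windows))) {
    i0 <- max(1L, floor(windows$start[i] * sr) + 1L)
    i1 <- min(nrow(filtered), ceiling(windows$end[i] * sr))
    seg <- filtered[i0:i1, , drop = FALSE]
    feats[i, ] <- apply(seg, 2, rms)
  }
  cbind(data.frame(label = windows$label, stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Split a feature table into a numeric matrix and its labels
#'
#' @param features data.frame as returned by [featurize()].
#' @return list with `X` (numeric matrix, rows = movements) and `labels`
#'   (character vector).
#' @export
feature_matrix <- function(features) {
  stopifnot("label" %in% names(features))
  X <- as.matrix(features[, setdiff(names(features), "label"), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, labels = as.character(features$label))
}
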