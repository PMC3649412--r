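#' Multi-channel sEMG recording container
#'
#' A `recording` is a fixed-rate block of synchronously sampled sEMG channels:
#' a numeric sample matrix (rows = time samples, columns = channels), the
#' sampling rate in Hz, ordered channel identifiers, and an opaque subject
#' label. The acquisition protocol this package targets samples each channel
#' at 1 kHz; the number of channels in routine use ranges from 2 to 8 pairs of
#' bipolar surface electrodes, though single-channel recordings are accepted
#' for component-level work.
#'
#' @param samples numeric matrix or data.frame, one column per channel, one
#'   row per sample. A bare vector is treated as a single channel.
#' @param sample_rate sampling rate in Hz (> 0); default 1000.
#' @param channel_ids character vector of channel labels (default
#'   `C0..C<k-1>`).
#' @param subject_id opaque subject label.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, sample_rate = 1000, channel_ids = NULL,
                      subject_id = NA_character_) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.vector(samples) && is.numeric(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (rows = samples, cols = channels)")
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  nch <- ncol(samples)
  if (nch < 1L || nch > 8L)
    stop("channel count must be between 1 and 8, got ", nch)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (is.null(channel_ids)) channel_ids <- paste0("C", seq_len(nch) - 1L)
  if (length(channel_ids) != nch)
    stop("channel_ids length must equal channel count")
  colnames(samples) <- channel_ids
  structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_ids = as.character(channel_ids), subject_id = subject_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.2f s)%s\n",
              ncol(x$samples), nrow(x$samples), x$sample_rate,
              recording_duration(x),
              if (is.na(x$subject_id)) "" else paste0(" subject=", x$subject_id)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  nrow(rec$samples) / rec$sample_rate
}

#' Select a subset of channels from a recording
#'
#' The classifier operates on an operator-selectable subset of 2-8 channels;
#' selection is by channel id.
#'
#' @param rec a [recording()].
#' @param channel_ids character vector of channel ids to keep, in the order
#'   requested.
#' @return a [recording()] restricted to the requested channels.
#' @export
select_channels <- function(rec, channel_ids) {
  stopifnot(inherits(rec, "recording"))
  missing_ch <- setdiff(channel_ids, rec$channel_ids)
  if (length(missing_ch))
    stop("unknown channel id(s): ", paste(missing_ch, collapse = ", "))
  recording(rec$samples[, channel_ids, drop = FALSE], rec$sample_rate,
            channel_ids, rec$subject_id)
}

#' Write / read a recording as delimited text
#'
#' The on-disk format is a plain CSV: a `# sample_rate: <Hz>` comment line,
#' then a header row of channel ids, then one row per sample. A cue schedule
#' is a CSV with columns `onset_s` and `movement_label`.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a [recording()].
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %.10g", rec$sample_rate), con)
  if (!is.na(rec$subject_id))
    writeLines(sprintf("# subject_id: %s", rec$subject_id), con)
  utils::write.csv(as.data.frame(rec$samples), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  header <- readLines(path, n = 5L)
  comments <- grep("^#", header, value = TRUE)
  sr_line <- grep("sample_rate", comments, value = TRUE)
  if (!length(sr_line)) stop("no '# sample_rate:' header comment in ", path)
  sample_rate <- as.numeric(sub(".*sample_rate:\\s*", "", sr_line[1]))
  subj_line <- grep("subject_id", comments, value = TRUE)
  subject_id <- if (length(subj_line))
    sub(".*subject_id:\\s*", "", subj_line[1]) else NA_character_
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  recording(as.matrix(dat), sample_rate, colnames(dat), subject_id)
}

#' @param cues data.frame with columns `onset_s` (seconds) and
#'   `movement_label`.
#' @rdname write_recording_csv
#' @export
write_cues_csv <- function(cues, path) {
  stopifnot(all(c("onset_s", "movement_label") %in% names(cues)))
  utils::write.csv(cues[, c("onset_s", "movement_label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_cues_csv <- function(path) {
  cues <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "movement_label") %in% names(cues)))
    stop("cue schedule must have columns onset_s and movement_label")
  cues
}
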