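# Standard 10-20 montage used throughout: 19 EEG channels plus the two EOG
# reference channels and the ECG channel recorded alongside them.
EEG_CHANNELS <- c("FP1", "FP2", "F3", "F4", "F7", "F8", "FZ",
                  "T7", "C3", "CZ", "C4", "T8",
                  "P7", "P3", "PZ", "P4", "P8", "O1", "O2")
EOG_CHANNELS <- c("EOGH", "EOGV")
ECG_CHANNEL <- "ECG"
ALL_CHANNELS <- c(EEG_CHANNELS, EOG_CHANNELS, ECG_CHANNEL)

#' Multichannel EEG recording
#'
#' Container for a labelled, uniformly sampled signal matrix with a phase tag
#' and reference-channel roles. Rows are channels, columns are samples.
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param labels character vector of channel names, one per row. Expected to
#'   use upper-case 10-20 names plus `EOGH`, `EOGV` and `ECG`.
#' @param rate sampling rate in samples/s (256 for the study hardware).
#' @param phase recording phase, `"resting"` (eyes closed) or `"active"`
#'   (cognitive task).
#' @param meta optional list of ground-truth metadata (event times, planted
#'   coupling) carried along by the simulator.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels, rate, phase = c("resting", "active"),
                          meta = list()) {
  phase <- match.arg(phase)
  data <- as.matrix(data)
  if (nrow(data) != length(labels))
    stop("number of rows of `data` (", nrow(data), ") must equal number of labels (",
         length(labels), ")")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  rownames(data) <- labels
  structure(list(data = data, labels = as.character(labels), rate = rate,
                 phase = phase, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), phase: %s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate, x$phase))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# pick channel rows by label, with a clear error naming missing channels
rec_channels <- function(rec, labels) {
  miss <- setdiff(labels, rec$labels)
  if (length(miss))
    stop("channel(s) missing from recording: ", paste(miss, collapse = ", "))
  rec$data[labels, , drop = FALSE]
}

#' Set of quasi-stationary segments
#'
#' Equal-length overlapping windows cut from a preprocessed recording, the
#' unit on which all spectral and marker estimation operates.
#'
#' @param segments list of channels x samples matrices of equal dimensions.
#' @param labels channel labels shared by every segment.
#' @param rate sampling rate in samples/s.
#' @param phase source recording phase.
#' @param length_s,overlap_s segment length and overlap in seconds
#'   (defaults 4 and 2).
#' @param starts integer start sample (1-based) of each segment in the source
#'   recording.
#' @param stationary logical flag per segment from the stationarity screen.
#' @param report list of pipeline diagnostics (windows excluded, segments
#'   kept/dropped, retained seconds).
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, rate, phase,
                        length_s = 4, overlap_s = 2,
                        starts = NULL, stationary = NULL, report = list()) {
  nsamp <- length_s * rate
  for (s in segments)
    if (nrow(s) != length(labels) || ncol(s) != nsamp)
      stop("every segment must be ", length(labels), " x ", nsamp)
  structure(list(segments = segments, labels = as.character(labels),
                 rate = rate, phase = phase,
                 length_s = length_s, overlap_s = overlap_s,
                 starts = starts, stationary = stationary, report = report),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s (%g s overlap), %d channels @ %g Hz, phase: %s\n",
              length(x$segments), x$length_s, x$overlap_s,
              length(x$labels), x$rate, x$phase))
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$segments)

# subset a segment_set to a channel set (by label), preserving metadata
segset_channels <- function(segs, labels) {
  idx <- match(labels, segs$labels)
  if (anyNA(idx))
    stop("channel(s) missing from segments: ",
         paste(labels[is.na(idx)], collapse = ", "))
  segs$segments <- lapply(segs$segments, function(m) m[idx, , drop = FALSE])
  segs$labels <- labels
  segs
}
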