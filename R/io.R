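# Reading and writing recordings and cohorts.
#
# Two interchange formats: a delimited-text matrix (header row of channel
# labels, one row per sample) and a minimal 16-bit EDF (European Data
# Format) with one-second data records, the de facto clinical EEG format.

edf_pad <- function(x, width) {
  s <- sprintf("%-*s", width, substr(as.character(x), 1, width))
  paste(s, collapse = "")
}

edf_num <- function(x, width) edf_pad(sub("\\.?0+$", "", sprintf("%.6f", x)), width)

#' Write a recording as EDF
#'
#' Minimal EDF writer: one-second data records, 16-bit samples, per-channel
#' physical scaling from the data range. The duration is truncated to whole
#' seconds if needed.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rate <- rec$rate
  data <- rec$data
  n <- ncol(data)
  n_rec <- n %/% rate
  if (n_rec * rate != n) {
    warning("truncating recording to ", n_rec, " whole seconds for EDF")
    data <- data[, seq_len(n_rec * rate), drop = FALSE]
  }
  ns <- nrow(data)
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32767; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80),
    edf_pad(paste("phase:", rec$phase), 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("HP:0.3Hz LP:70Hz N:50Hz", 80), ns), collapse = ""),
    paste(rep(edf_pad(rate, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      d <- round((data[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @param phase phase tag to attach (read from the recording-id field when
#'   present).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, phase = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8)                       # version
  rd(80)                      # patient
  recid <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates in EDF are not supported")
  rate <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, idx] <- (d - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
    }
  }
  if (is.null(phase)) {
    phase <- if (grepl("active", recid)) "active" else "resting"
  }
  eeg_recording(data, toupper(labels), rate, phase)
}

#' Write a recording as a delimited-text matrix
#'
#' Header row of channel labels, one tab-separated row per sample.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$labels
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording
#'
#' Reads EDF or delimited text, normalizes channel labels to upper case and
#' validates them against the expected montage (19 EEG plus EOGH, EOGV, ECG).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"edf"` or `"tsv"`.
#' @param rate sampling rate for text input (EDF carries its own).
#' @param phase phase tag for text input.
#' @param validate require the full expected montage (default TRUE).
#' @return An [eeg_recording()] with channels in montage order.
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv"),
                           rate = 256, phase = "resting", validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  rec <- if (format == "edf") {
    read_edf(path, phase = NULL)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    eeg_recording(t(as.matrix(df)), toupper(colnames(df)), rate, phase)
  }
  if (validate) {
    unknown <- setdiff(rec$labels, ALL_CHANNELS)
    if (length(unknown))
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
           "; expected: ", paste(ALL_CHANNELS, collapse = ", "))
    miss <- setdiff(ALL_CHANNELS, rec$labels)
    if (length(miss))
      stop("required channel(s) missing: ", paste(miss, collapse = ", "))
    rec$data <- rec$data[ALL_CHANNELS, , drop = FALSE]
    rec$labels <- ALL_CHANNELS
  }
  rec
}

#' Write and read a cohort table
#'
#' CSV with columns `id`, `mmse`, `age`, `sex`, `education`, `ad_duration`
#' (plus any extra columns such as the planted `coupling`).
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `path` (write) / the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "mmse", "age", "sex", "education", "ad_duration")
  miss <- setdiff(need, names(co))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  co
}
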