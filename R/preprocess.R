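# Artifact removal and segmentation.
#
# Six-stage chain: amplitude pre-selection, 2-Hz high-pass, ECG-guided
# cardiac template subtraction, EOG regression (after 12-Hz low-pass of the
# EOG), 15-Hz low-pass, and segmentation into 4-s windows with 2-s overlap
# screened by an augmented Dickey-Fuller stationarity test.

# zero-phase FIR application: FFT convolution followed by group-delay
# compensation of order/2 samples; x may be a vector or channels x samples
# matrix, output has the same shape
apply_fir <- function(x, h) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(X)
  nh <- length(h)
  d <- (nh - 1L) %/% 2L
  L <- stats::nextn(n + nh, 2)
  H <- stats::fft(c(h, numeric(L - nh)))
  Xp <- rbind(t(X), matrix(0, L - n, nrow(X)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)) / L
  out <- t(Y[(d + 1L):(d + n), , drop = FALSE])
  dimnames(out) <- dimnames(X)
  if (vec) as.numeric(out) else out
}

#' Linear-phase FIR filtering
#'
#' Designs a windowed-sinc (Hamming) FIR filter of even order and applies it
#' with delay compensation, so the output is aligned with the input. Passband
#' gain is within +-0.05 of unity and stopband attenuation exceeds 40 dB
#' beyond the transition band.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param mode `"highpass"` or `"lowpass"`.
#' @param cutoff border frequency in Hz (must be below Nyquist).
#' @param rate sampling rate in samples/s.
#' @param order filter order (even), default 340.
#' @return Filtered signal with the shape of `x`.
#' @export
fir_filter <- function(x, mode = c("highpass", "lowpass"), cutoff,
                       rate = 256, order = 340) {
  mode <- match.arg(mode)
  if (cutoff >= rate / 2) stop("`cutoff` must be below the Nyquist frequency")
  if (order %% 2 != 0) stop("`order` must be even (linear-phase type I)")
  h <- as.numeric(signal::fir1(order, cutoff / (rate / 2),
                               if (mode == "highpass") "high" else "low"))
  # constrain the high-pass to an exact spectral null at DC (the Hamming
  # stopband floor alone leaves ~2e-3 of a constant input)
  if (mode == "highpass") h <- h - sum(h) / length(h)
  apply_fir(x, h)
}

#' R-peak detection on an ECG channel
#'
#' Pan-Tompkins style QRS detector: band-pass (5-18 Hz), centered five-point
#' derivative, squaring, 150-ms moving-window integration, then adaptive
#' signal/noise thresholding with a 200-ms refractory period. Peak locations
#' are refined to the ECG maximum near each integration peak.
#'
#' @param ecg numeric ECG series (>= 2 s).
#' @param rate sampling rate in samples/s.
#' @return Strictly increasing integer sample indices of detected R peaks;
#'   empty (with a warning) for a flat signal.
#' @export
detect_r_peaks <- function(ecg, rate = 256) {
  n <- length(ecg)
  if (n < 2 * rate) stop("ECG must be at least 2 s long")
  if (stats::sd(ecg) < .Machine$double.eps^0.5 * (1 + max(abs(ecg)))) {
    warning("flat ECG signal: no R peaks detected")
    return(integer(0))
  }
  h <- signal::fir1(96, c(5, 18) / (rate / 2), "pass")
  bp <- apply_fir(ecg, as.numeric(h))
  der <- as.numeric(stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  w <- round(0.15 * rate)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate local maxima of the integrated energy
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) {
    warning("no QRS-like energy found in ECG")
    return(integer(0))
  }
  refractory <- round(0.2 * rate)
  spki <- max(mwi[seq_len(min(n, 2 * rate))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * rate))]) * 0.5
  peaks <- integer(0)
  last <- -refractory
  for (c0 in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[c0] >= thr && (c0 - last) >= refractory) {
      peaks <- c(peaks, c0)
      last <- c0
      spki <- 0.125 * mwi[c0] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[c0] + 0.875 * npki
    }
  }
  if (!length(peaks)) return(integer(0))
  # refine to the ECG extremum in a +-75 ms neighbourhood
  half <- round(0.075 * rate)
  ref <- vapply(peaks, function(p) {
    i <- max(1L, p - half):min(n, p + half)
    i[which.max(abs(ecg[i]))]
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce the refractory rule after refinement
  keep <- c(TRUE, diff(ref) >= refractory)
  while (!all(keep)) {
    ref <- ref[keep]
    keep <- c(TRUE, diff(ref) >= refractory)
  }
  ref
}

#' Cardiac artifact removal by template subtraction
#'
#' Estimates, per EEG channel, the average waveform in a +-150 ms window
#' around the detected R peaks and subtracts it at every peak. Channels are
#' untouched where no complete peak window applies; with no peaks the input
#' is returned unchanged.
#'
#' @param data channels x samples numeric matrix.
#' @param r_peaks integer sample indices from [detect_r_peaks()].
#' @param rate sampling rate in samples/s.
#' @return Matrix of the same shape with peri-peak cardiac averages removed.
#' @export
remove_cardiac <- function(data, r_peaks, rate = 256) {
  if (!length(r_peaks)) return(data)
  half <- round(0.15 * rate)
  n <- ncol(data)
  full <- r_peaks[r_peaks - half >= 1 & r_peaks + half <= n]
  if (!length(full)) return(data)
  idx <- vapply(full, function(p) (p - half):(p + half), integer(2 * half + 1))
  out <- data
  for (ch in seq_len(nrow(data))) {
    seg <- matrix(data[ch, idx], nrow = 2 * half + 1)
    tmpl <- rowMeans(seg)
    out[ch, as.vector(idx)] <- data[ch, as.vector(idx)] - rep(tmpl, length(full))
  }
  out
}

#' Ocular artifact removal by static EOG regression
#'
#' Regresses each EEG channel on the two (low-pass filtered) EOG channels
#' plus an intercept by ordinary least squares and keeps the residual. The
#' EOG regressors should first be low-pass filtered at 12 Hz so that neuronal
#' activity leaked into the EOG is not regressed out of the EEG.
#'
#' @param data channels x samples EEG matrix.
#' @param eog 2 x samples matrix of filtered EOG channels.
#' @return List with `data` (cleaned EEG), `weights` (channels x regressors
#'   coefficient matrix) and `dropped` (index of an EOG channel dropped for
#'   collinearity, if any).
#' @export
remove_ocular <- function(data, eog) {
  if (nrow(eog) != 2) stop("`eog` must have two rows")
  Z <- cbind(1, t(eog))
  qz <- qr(Z)
  dropped <- integer(0)
  if (qz$rank < ncol(Z)) {
    warning("collinear EOG channels: dropping the second EOG regressor")
    dropped <- 2L
    Z <- Z[, 1:2, drop = FALSE]
    qz <- qr(Z)
  }
  B <- qr.coef(qz, t(data))          # regressors x channels
  resid <- t(data) - Z %*% B
  list(data = t(resid), weights = t(B), dropped = dropped)
}

#' Cut a recording into overlapping quasi-stationary segments
#'
#' Divides the signal into windows of `length_s` seconds advancing by
#' `length_s - overlap_s` seconds; trailing samples that do not fill a window
#' are discarded. A 180-s recording at 256 Hz yields 89 segments.
#'
#' @param rec an [eeg_recording()] (or channels x samples matrix plus `rate`).
#' @param length_s window length in seconds (default 4).
#' @param overlap_s window overlap in seconds (default 2).
#' @return A [segment_set()].
#' @export
segment_recording <- function(rec, length_s = 4, overlap_s = 2) {
  data <- rec$data; rate <- rec$rate
  L <- round(length_s * rate)
  step <- round((length_s - overlap_s) * rate)
  n <- ncol(data)
  if (n < L) stop("recording shorter than one segment (", length_s, " s)")
  starts <- seq(1L, n - L + 1L, by = step)
  segs <- lapply(starts, function(s) data[, s:(s + L - 1L), drop = FALSE])
  segment_set(segs, rownames(data), rate, rec$phase,
              length_s = length_s, overlap_s = overlap_s, starts = starts)
}

# amplitude pre-selection: stand-in for the study's visual rejection of
# non-removable artifacts. Flags fixed windows in which any channel exceeds
# `k` times its own median absolute deviation; returns a per-sample logical
# mask of bad samples.
preselect_mask <- function(data, rate, window_s = 4, k = 8) {
  n <- ncol(data)
  madv <- apply(data, 1, function(x) stats::mad(x))
  madv[madv <= 0] <- .Machine$double.eps
  thr <- k * madv
  L <- round(window_s * rate)
  starts <- seq(1L, n - L + 1L, by = L)
  bad <- logical(n)
  for (s in starts) {
    w <- s:(s + L - 1L)
    if (any(abs(data[, w, drop = FALSE]) > thr)) bad[w] <- TRUE
  }
  # trailing partial window judged with the same rule
  if (max(starts) + L - 1L < n) {
    w <- (max(starts) + L):n
    if (any(abs(data[, w, drop = FALSE]) > thr)) bad[w] <- TRUE
  }
  bad
}

#' Full preprocessing pipeline
#'
#' Runs the artifact-removal chain in fixed order: amplitude pre-selection
#' (an automatic surrogate for visual rejection), 2-Hz high-pass of all
#' channels, cardiac template subtraction guided by ECG R peaks, ocular
#' regression on 12-Hz low-passed EOG, 15-Hz low-pass, segmentation into 4-s
#' windows with 2-s overlap, and a per-channel augmented Dickey-Fuller screen
#' that drops non-stationary segments. Segments overlapping pre-selected bad
#' samples are excluded.
#'
#' @param rec an [eeg_recording()] containing the 19 EEG channels plus EOG
#'   and ECG reference channels.
#' @param highpass,lowpass EEG band edges in Hz (defaults 2 and 15).
#' @param eog_lowpass EOG low-pass border in Hz (default 12).
#' @param fir_order FIR order for all filters (default 340).
#' @param length_s,overlap_s segmentation parameters (defaults 4 and 2).
#' @param preselect_window,preselect_mad pre-selection window length (s) and
#'   MAD multiplier (defaults 4 and 8).
#' @param adf_max_lag,adf_level,adf_min_frac stationarity screen: maximum ADF
#'   lag order (AIC-selected), test level, and minimum fraction of channels
#'   that must reject the unit root for a segment to be kept.
#' @return A [segment_set()] of band-limited EEG segments (19 channels); its
#'   `report` records windows excluded, retained seconds and ADF drops.
#' @export
preprocess_pipeline <- function(rec, highpass = 2, lowpass = 15,
                                eog_lowpass = 12, fir_order = 340,
                                length_s = 4, overlap_s = 2,
                                preselect_window = 4, preselect_mad = 8,
                                adf_max_lag = 10, adf_level = 0.05,
                                adf_min_frac = 0.9) {
  rate <- rec$rate
  eeg <- rec_channels(rec, EEG_CHANNELS)
  eog <- rec_channels(rec, EOG_CHANNELS)
  ecg <- as.numeric(rec_channels(rec, ECG_CHANNEL))

  # 1. pre-selection on the raw EEG (the EOG/ECG references are spiky by
  # nature and are not grounds for exclusion)
  bad <- preselect_mask(eeg, rate,
                        window_s = preselect_window, k = preselect_mad)
  excluded_s <- sum(bad) / rate
  retained_s <- (length(bad) - sum(bad)) / rate

  # 2. high-pass all channels
  eeg <- fir_filter(eeg, "highpass", highpass, rate, fir_order)
  eog <- fir_filter(eog, "highpass", highpass, rate, fir_order)
  ecg <- fir_filter(ecg, "highpass", highpass, rate, fir_order)

  # 3. cardiac removal
  r_peaks <- detect_r_peaks(ecg, rate)
  eeg <- remove_cardiac(eeg, r_peaks, rate)

  # 4. ocular removal on 12-Hz low-passed EOG
  eog_f <- fir_filter(eog, "lowpass", eog_lowpass, rate, fir_order)
  eeg <- remove_ocular(eeg, eog_f)$data

  # 5. low-pass
  eeg <- fir_filter(eeg, "lowpass", lowpass, rate, fir_order)

  # 6. segmentation
  segs <- segment_recording(
    eeg_recording(eeg, EEG_CHANNELS, rate, rec$phase),
    length_s = length_s, overlap_s = overlap_s)
  L <- round(length_s * rate)
  clean <- vapply(segs$starts, function(s) !any(bad[s:(s + L - 1L)]), logical(1))

  # 7. stationarity screen
  stat_frac <- vapply(seq_along(segs$segments), function(i) {
    if (!clean[i]) return(NA_real_)
    m <- segs$segments[[i]]
    mean(vapply(seq_len(nrow(m)), function(ch)
      adf_stationary(m[ch, ], max_lag = adf_max_lag, level = adf_level)$stationary,
      logical(1)))
  }, numeric(1))
  stationary <- !is.na(stat_frac) & stat_frac >= adf_min_frac
  keep <- clean & stationary

  report <- list(n_segments_raw = length(segs$segments),
                 n_excluded_preselect = sum(!clean),
                 n_dropped_adf = sum(clean & !stationary),
                 n_kept = sum(keep),
                 excluded_seconds = excluded_s,
                 retained_seconds = retained_s,
                 n_r_peaks = length(r_peaks))
  if (!any(keep))
    stop("all segments rejected (", report$n_excluded_preselect,
         " by pre-selection, ", report$n_dropped_adf, " by the ADF screen)")
  segment_set(segs$segments[keep], EEG_CHANNELS, rate, rec$phase,
              length_s = length_s, overlap_s = overlap_s,
              starts = segs$starts[keep],
              stationary = stationary[keep], report = report)
}
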