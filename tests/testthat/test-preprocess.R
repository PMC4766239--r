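# Artifact removal and segmentation

test_that("FIR filters meet their passband and stopband obligations", {
  rate <- 256
  n <- 20 * rate
  t <- seq_len(n) / rate
  interior <- (3 * rate):(n - 3 * rate)
  # DC is annihilated by the 2-Hz high-pass
  hp <- fir_filter(rep(1, n), "highpass", 2, rate)
  expect_lt(max(abs(hp[interior])), 1e-3)
  # a 10-Hz tone passes the 2/15-Hz chain at unit gain
  s10 <- sin(2 * pi * 10 * t)
  y <- fir_filter(fir_filter(s10, "highpass", 2, rate), "lowpass", 15, rate)
  amp <- max(abs(y[interior]))
  expect_gt(amp, 0.9); expect_lt(amp, 1.1)
  # a 25-Hz tone is suppressed by the 15-Hz low-pass
  s25 <- sin(2 * pi * 25 * t)
  y25 <- fir_filter(s25, "lowpass", 15, rate)
  expect_lt(max(abs(y25[interior])), 0.05)
  expect_error(fir_filter(s10, "lowpass", 130, rate), "Nyquist")
  expect_error(fir_filter(s10, "lowpass", 15, rate, order = 341), "even")
})

test_that("filtering is delay-compensated and applied per channel", {
  set.seed(1)
  X <- matrix(rnorm(2 * 4096), 2, dimnames = list(c("A", "B"), NULL))
  Y <- fir_filter(X, "lowpass", 30, 256)
  expect_identical(rownames(Y), c("A", "B"))
  # delay compensation: cross-correlation of a band-limited input with its
  # filtered copy peaks at lag 0
  x <- fir_filter(rnorm(4096), "lowpass", 20, 256)
  y <- fir_filter(x, "lowpass", 30, 256)
  cc <- stats::ccf(x[500:3500], y[500:3500], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("R-peak detection recovers planted spikes", {
  rate <- 256
  n <- 30 * rate
  times <- round(seq(rate / 2, n - 30, by = rate / 1.2))
  set.seed(2)
  ecg <- 25 * spike_train(n, times) + rnorm(n, sd = 0.01)
  found <- detect_r_peaks(ecg, rate)
  # every planted peak found within +-2 samples, no extras
  expect_equal(length(found), length(times))
  expect_true(all(vapply(times, function(t0) min(abs(found - t0)) <= 2,
                         logical(1))))
  expect_true(all(diff(found) >= 0.2 * rate))
  # flat signal: empty with warning
  expect_warning(empty <- detect_r_peaks(numeric(3 * rate), rate), "flat")
  expect_length(empty, 0)
  expect_error(detect_r_peaks(rnorm(100), rate), "2 s")
})

test_that("R-peak sensitivity stays high at 10 dB SNR", {
  rate <- 256
  n <- 60 * rate
  times <- round(seq(rate / 2, n - 30, by = rate / 1.2))
  sig <- 25 * spike_train(n, times)
  noise_sd <- sqrt(stats::var(sig) / 10)
  sens <- vapply(1:20, function(s) {
    set.seed(s)
    found <- detect_r_peaks(sig + rnorm(n, sd = noise_sd), rate)
    mean(vapply(times, function(t0) any(abs(found - t0) <= 10), logical(1)))
  }, numeric(1))
  expect_gte(mean(sens), 0.95)
})

test_that("cardiac template subtraction removes peri-peak artifact power", {
  rate <- 256
  n <- 120 * rate
  set.seed(8)
  neural <- as.numeric(stats::filter(rnorm(n, sd = 0.8), 0.6,
                                     method = "recursive"))
  times <- round(seq(rate / 2, n - 30, by = rate / 1.2 * 1.02))
  train <- spike_train(n, times)
  eeg <- rbind(ch = neural + 1.5 * train)
  cleaned <- remove_cardiac(eeg, times, rate)
  half <- round(0.15 * rate)
  inner <- times[times > half & times < n - half]
  w <- unlist(lapply(inner, function(p) (p - half):(p + half)))
  ratio <- sum((cleaned[1, w] - neural[w])^2) / sum((eeg[1, w] - neural[w])^2)
  expect_lte(ratio, 0.1)
  # no peaks: exact identity
  expect_identical(remove_cardiac(eeg, integer(0), rate), eeg)
  # clean EEG barely changes when peaks are subtracted anyway
  clean <- rbind(ch = neural)
  out <- remove_cardiac(clean, times, rate)
  expect_lte(sqrt(mean((out - clean)^2)) / sqrt(mean(clean^2)), 0.05)
})

test_that("ocular regression recovers the leak weight and orthogonalizes", {
  rate <- 256
  n <- 120 * rate
  set.seed(8)
  neural <- as.numeric(stats::filter(rnorm(n, sd = 0.8), 0.6,
                                     method = "recursive"))
  bt <- sort(sample(200:(n - 200), 25))
  blink <- blink_train(n, bt, rate, amp = 6)
  eeg <- rbind(ch = neural + 0.8 * blink)
  eog <- rbind(e1 = blink + rnorm(n, sd = 0.05), e2 = rnorm(n))
  eogf <- fir_filter(eog, "lowpass", 12, rate)
  res <- remove_ocular(eeg, eogf)
  expect_lt(abs(res$weights[1, 2] - 0.8), 0.05)
  # >= 90 % of the blink contamination power is removed
  ratio <- sum((res$data[1, ] - neural)^2) / sum((eeg[1, ] - neural)^2)
  expect_lte(ratio, 0.1)
  # residuals exactly orthogonal to the regressors (OLS normal equations)
  g <- tcrossprod(res$data, eogf)
  expect_lt(max(abs(g)) / n, 1e-8)
  # orthogonal EOG leaves the EEG essentially untouched
  set.seed(9)
  eog0 <- matrix(rnorm(2 * n), 2)
  res0 <- remove_ocular(eeg, eog0)
  expect_lt(max(abs(res0$weights[1, 2:3])), 0.01)
  # output equals input up to the fitted intercept (means are removed later
  # per segment anyway)
  ctr <- eeg - rowMeans(eeg)
  expect_lt(sqrt(mean((res0$data - ctr)^2)) / stats::sd(eeg), 0.02)
  # collinear EOG channels: one is dropped with a warning
  expect_warning(remove_ocular(eeg, rbind(eogf[1, ], eogf[1, ])), "collinear")
})

test_that("segmentation follows the floor count with discarded remainder", {
  mk <- function(secs) eeg_recording(matrix(rnorm(secs * 256), 1), "C3", 256,
                                     "resting")
  expect_length(segment_recording(mk(180))$segments, 89)
  expect_length(segment_recording(mk(4))$segments, 1)
  expect_length(segment_recording(mk(5))$segments, 1)
  expect_length(segment_recording(mk(10))$segments, 4)
  s <- segment_recording(mk(20))
  expect_true(all(diff(s$starts) == 2 * 256))
  expect_true(all(vapply(s$segments, ncol, 0L) == 1024))
  expect_error(segment_recording(mk(3)), "shorter")
})

test_that("ADF screen separates noise from random walks", {
  set.seed(11)
  wn <- mean(replicate(100, adf_stationary(rnorm(1024))$stationary))
  rw <- mean(replicate(100, adf_stationary(cumsum(rnorm(1024)))$stationary))
  expect_gte(wn, 0.95)
  expect_lte(rw, 0.10)
  expect_error(adf_stationary(rep(1, 1024)), "constant")
  expect_error(adf_stationary(rnorm(20)), "short")
})

test_that("pipeline keeps clean data, drops saturated blocks, stays in band", {
  rec <- generate_recording(list(mmse = 20), "resting", artifacts_off(),
                            seed = 21, duration_s = 40)
  segs <- preprocess_pipeline(rec)
  expect_gte(segs$report$n_kept / segs$report$n_segments_raw, 0.95)
  expect_identical(segs$labels, eegsynch:::EEG_CHANNELS)
  # saturated 10-s block is excluded by pre-selection
  bad <- rec
  blk <- (15 * 256 + 1):(25 * 256)
  bad$data["C3", blk] <- 1e4
  segs_b <- preprocess_pipeline(bad)
  ends <- segs_b$starts + 1024 - 1
  expect_true(all(ends < min(blk) | segs_b$starts > max(blk)))
  # out-of-band spectral power of kept segments is marginal
  frac <- vapply(segs$segments[1:5], function(m) {
    x <- m[3, ] - mean(m[3, ])
    P <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 256 / length(x)
    keep <- f <= 128
    sum(P[keep][f[keep] < 2 | f[keep] > 15]) / sum(P[keep])
  }, numeric(1))
  expect_lte(max(frac), 0.05)
})

test_that("band-pass stages are idempotent for mid-band content", {
  set.seed(3)
  x <- matrix(as.numeric(stats::filter(
    rnorm(30 * 256), eegsynch:::ar2_coef(9.5, 0.97, 256),
    method = "recursive")), 1)
  # confine the probe to the flat passband: content inside the 2/15-Hz
  # transition bands is re-attenuated on every pass by construction
  x <- fir_filter(fir_filter(x, "highpass", 4), "lowpass", 13)
  y1 <- fir_filter(fir_filter(x, "highpass", 2), "lowpass", 15)
  y2 <- fir_filter(fir_filter(y1, "highpass", 2), "lowpass", 15)
  i <- 1024:(ncol(x) - 1024)
  expect_lte(sqrt(mean((y2[, i] - y1[, i])^2)) / sqrt(mean(y1[, i]^2)), 0.01)
})
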