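# Synthetic cohorts and recordings.
#
# The generator emulates the statistical structure the analysis assumes:
# five spatial channel clusters each dominated by two latent AR(2) sources
# (so the first two principal components carry >90 % of cluster variance),
# a shared cross-cluster source whose mixing weight follows an inverted-U
# function of MMSE, and physiological artifacts (cardiac, ocular, muscle,
# drift) with co-recorded ECG/EOG reference channels.

#' Cohort specification
#'
#' Parameters of the simulated patient cohort. The coupling parameters plant
#' an inverted-U dependence of cross-cluster synchrony on MMSE:
#' `k(mmse) = coupling_max + coupling_curvature * (mmse - coupling_peak)^2`,
#' clipped to \[0, 1\].
#'
#' @param n_subjects number of subjects (>= 3; regression needs residual
#'   degrees of freedom).
#' @param mmse_range inclusive integer MMSE interval, default 15-26 as in the
#'   probable-AD population the generator emulates.
#' @param coupling_peak MMSE value at the planted quadratic vertex (default 21).
#' @param coupling_curvature quadratic coefficient; negative for an inverted U.
#' @param coupling_max coupling weight attained at the vertex, in \[0, 1\].
#' @param seed integer RNG seed making the cohort reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 79, mmse_range = c(15L, 26L),
                        coupling_peak = 21, coupling_curvature = -0.01,
                        coupling_max = 0.6, seed = 1L) {
  if (n_subjects < 3) stop("`n_subjects` must be at least 3")
  mmse_range <- as.integer(round(mmse_range))
  if (length(mmse_range) != 2L || mmse_range[1] > mmse_range[2] ||
      mmse_range[1] < 0L || mmse_range[2] > 30L)
    stop("`mmse_range` must be an ordered integer interval within 0-30")
  if (!is.finite(coupling_curvature)) stop("`coupling_curvature` must be finite")
  structure(list(n_subjects = as.integer(n_subjects), mmse_range = mmse_range,
                 coupling_peak = coupling_peak,
                 coupling_curvature = coupling_curvature,
                 coupling_max = coupling_max, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Planted coupling as a function of MMSE
#'
#' Evaluates the inverted-U coupling curve of a [cohort_spec()] at given MMSE
#' scores. This is the ground-truth link between disease severity and
#' cross-cluster synchrony that the downstream regression is meant to recover.
#'
#' @param mmse integer MMSE score(s) within `spec$mmse_range`.
#' @param spec a [cohort_spec()].
#' @return Coupling coefficient(s) in \[0, 1\].
#' @export
coupling_curve <- function(mmse, spec = cohort_spec()) {
  if (any(mmse < spec$mmse_range[1] | mmse > spec$mmse_range[2]))
    stop("`mmse` outside the cohort's MMSE range ",
         spec$mmse_range[1], "-", spec$mmse_range[2])
  k <- spec$coupling_max + spec$coupling_curvature * (mmse - spec$coupling_peak)^2
  pmin(pmax(k, 0), 1)
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject: MMSE (with every score of the range represented
#' once the cohort is at least as large as the range), age 52-88, sex with the
#' approximate 63/37 female/male split of the emulated population, education
#' level 1-6 and AD duration 2-120 months. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `id`, `mmse`, `age`, `sex`, `education`,
#'   `ad_duration` and the planted ground-truth `coupling`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  lo <- spec$mmse_range[1]; hi <- spec$mmse_range[2]
  width <- hi - lo + 1L
  mmse <- if (n >= width) {
    c(lo:hi, sample(lo:hi, n - width, replace = TRUE))
  } else {
    sample(lo:hi, n, replace = TRUE)
  }
  mmse <- sample(mmse)  # shuffle so id order carries no MMSE structure
  cohort <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    mmse = as.integer(mmse),
    age = sample(52:88, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.63, 0.37)),
    education = sample(1:6, n, replace = TRUE),
    ad_duration = sample(2:120, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cohort$coupling <- coupling_curve(cohort$mmse, spec)
  cohort
}

#' Artifact specification for the simulator
#'
#' Rates, amplitudes and on/off flags of the injected physiological artifacts.
#' Amplitudes are in the same (arbitrary) units as the neuronal sources, which
#' have unit variance.
#'
#' @param cardiac_rate heart rate in beats/s (default 1.2, i.e. 72 bpm).
#' @param cardiac_amplitude peak amplitude of the cardiac spike leaked into
#'   EEG channels; the ECG channel carries the same template at amplitude 25.
#' @param blink_rate Poisson rate of blink events in events/s.
#' @param blink_amplitude peak amplitude of the 300-ms raised-cosine blink
#'   pulse in the EOG channels; EEG channels receive frontally weighted copies.
#' @param muscle_band frequency band (Hz) of the muscle-tension noise, above
#'   the 15-Hz analysis band so the low-pass stage can remove it.
#' @param muscle_amplitude standard deviation of the muscle noise in the
#'   temporal channels.
#' @param drift_band frequency band (Hz) of slow electrode/transpiration
#'   drift, below the 2-Hz high-pass edge.
#' @param drift_amplitude standard deviation of the drift component.
#' @param cardiac,blink,muscle,drift logical on/off flags.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(cardiac_rate = 1.2, cardiac_amplitude = 0.35,
                          blink_rate = 0.2, blink_amplitude = 6,
                          muscle_band = c(20, 45), muscle_amplitude = 0.4,
                          drift_band = c(0, 0.5), drift_amplitude = 1.5,
                          cardiac = TRUE, blink = TRUE,
                          muscle = TRUE, drift = TRUE) {
  if (cardiac_rate < 0 || blink_rate < 0)
    stop("artifact rates must be non-negative")
  if (muscle_band[1] >= muscle_band[2] || drift_band[1] >= drift_band[2])
    stop("artifact bands must be ordered intervals")
  if (muscle_band[1] < 15)
    stop("`muscle_band` must lie above 15 Hz")
  if (drift_band[2] > 2)
    stop("`drift_band` must lie below 2 Hz")
  structure(list(cardiac_rate = cardiac_rate,
                 cardiac_amplitude = cardiac_amplitude,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 muscle_band = muscle_band, muscle_amplitude = muscle_amplitude,
                 drift_band = drift_band, drift_amplitude = drift_amplitude,
                 cardiac = cardiac, blink = blink, muscle = muscle,
                 drift = drift),
            class = "artifact_spec")
}

#' @rdname artifact_spec
#' @export
artifacts_off <- function() {
  artifact_spec(cardiac = FALSE, blink = FALSE, muscle = FALSE, drift = FALSE)
}

# --- latent source machinery ------------------------------------------------

# AR(2) with a spectral resonance at f0 Hz and pole modulus r (< 1, stable by
# construction). Innovations are scaled so the stationary variance is 1.
ar2_coef <- function(f0, r, rate) {
  stopifnot(r > 0, r < 1)
  c(2 * r * cos(2 * pi * f0 / rate), -r^2)
}

ar2_sd1 <- function(a) {
  # stationary variance of AR(2): gamma0 = s2*(1-a2) / ((1+a2)((1-a2)^2-a1^2))
  a1 <- a[1]; a2 <- a[2]
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  sqrt(1 / v)  # innovation sd giving unit stationary variance
}

simulate_ar2 <- function(n, f0, r, rate, burn = 512L) {
  a <- ar2_coef(f0, r, rate)
  if (min(Mod(polyroot(c(1, -a)))) <= 1)
    stop("unstable AR source configuration (f0 = ", f0, ", r = ", r, ")")
  e <- rnorm(n + burn, sd = ar2_sd1(a))
  as.numeric(stats::filter(e, a, method = "recursive"))[(burn + 1):(burn + n)]
}

# per-cluster generator constants: resonances (Hz) of the two private sources
# and the loading patterns mapping the sources onto the cluster's channels
GEN_F1 <- c(Anterior = 9.5, TemporalLeft = 8.5, Central = 10.5,
            TemporalRight = 11.0, Posterior = 9.0)
GEN_F2 <- c(Anterior = 5.0, TemporalLeft = 4.5, Central = 6.0,
            TemporalRight = 6.5, Posterior = 5.5)
GEN_R1 <- 0.97
GEN_R2 <- 0.95
GEN_SHARED_F <- 10     # Hz, alpha-range shared source carrying the coupling
GEN_SHARED_R <- 0.96
GEN_NOISE_SD <- 0.15   # per-channel sensor noise

# frontally dominated blink leakage into EEG channels (fraction of the EOG
# pulse amplitude reaching each scalp site)
BLINK_GAINS <- c(FP1 = 1.0, FP2 = 1.0, F3 = 0.5, F4 = 0.5, F7 = 0.45,
                 F8 = 0.45, FZ = 0.35, T7 = 0.1, C3 = 0.15, CZ = 0.15,
                 C4 = 0.15, T8 = 0.1, P7 = 0.05, P3 = 0.05, PZ = 0.05,
                 P4 = 0.05, P8 = 0.05, O1 = 0.05, O2 = 0.05)

# raised-cosine blink pulse, 300 ms, band-limited well below 10 Hz
blink_pulse <- function(rate, width_s = 0.3) {
  n <- round(width_s * rate)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# cardiac spike template: second-derivative-of-Gaussian (Ricker) wavelet,
# peaked at the event time so detected R peaks align with ground truth
cardiac_template <- function(rate, sigma_s = 0.02, half_s = 0.1) {
  h <- round(half_s * rate)
  t <- (-h:h) / rate
  (1 - (t / sigma_s)^2) * exp(-t^2 / (2 * sigma_s^2))
}

# place a template at given sample indices in a zero vector of length n
place_events <- function(n, centers, template) {
  x <- numeric(n)
  half <- (length(template) - 1L) %/% 2L
  for (c0 in centers) {
    i <- (c0 - half):(c0 + half)
    keep <- i >= 1L & i <= n
    x[i[keep]] <- x[i[keep]] + template[keep]
  }
  x
}

#' Generate a synthetic multichannel recording
#'
#' Simulates one subject-phase recording: 19 EEG channels built from two
#' cluster-private AR(2) sources plus a shared alpha-range source whose mixing
#' weight is [coupling_curve()] of the subject's MMSE, two EOG channels and an
#' ECG channel, with artifacts injected per `artifacts`. The shared source
#' enters cluster `c` with a lag of `c - 1` samples, so coupled clusters have
#' a nonzero Granger direction as well as coherence.
#'
#' @param subject one-row data.frame or list with at least an `mmse` field
#'   (see [generate_cohort()]).
#' @param phase `"resting"` (180 s) or `"active"` (130 s).
#' @param artifacts an [artifact_spec()].
#' @param seed integer seed; the same (subject, phase, seed) reproduces the
#'   signal matrix bit-identically.
#' @param spec the [cohort_spec()] supplying the coupling curve.
#' @param duration_s optional duration override in seconds.
#' @param rate sampling rate, default 256 samples/s.
#' @return An [eeg_recording()] whose `meta` carries ground truth: the
#'   coupling weight, artifact event times and the clean (artifact-free)
#'   signal matrix is recoverable by regenerating with [artifacts_off()].
#' @export
generate_recording <- function(subject, phase = c("resting", "active"),
                               artifacts = artifact_spec(), seed = 1L,
                               spec = cohort_spec(), duration_s = NULL,
                               rate = 256) {
  phase <- match.arg(phase)
  if (is.null(duration_s))
    duration_s <- if (phase == "resting") 180 else 130
  k <- coupling_curve(subject$mmse, spec)
  set.seed(as.integer(seed))
  n <- round(duration_s * rate)

  # latent sources
  shared <- simulate_ar2(n + 8L, GEN_SHARED_F, GEN_SHARED_R, rate)
  cl_names <- names(CLUSTERS)
  X <- matrix(0, length(EEG_CHANNELS), n, dimnames = list(EEG_CHANNELS, NULL))
  s1_anterior <- NULL
  for (ci in seq_along(cl_names)) {
    cl <- cl_names[ci]
    chans <- CLUSTERS[[cl]]
    m <- length(chans)
    s1 <- simulate_ar2(n, GEN_F1[[cl]], GEN_R1, rate)
    s2 <- simulate_ar2(n, GEN_F2[[cl]], GEN_R2, rate)
    if (ci == 1L) s1_anterior <- s1
    u <- shared[(8L - (ci - 1L) + 1L):(8L - (ci - 1L) + n)]  # lag ci-1 samples
    s1c <- s1 + k * u
    L1 <- seq(1.0, 0.8, length.out = m)
    L2 <- 0.6 * (-1)^(seq_len(m) - 1L)
    X[chans, ] <- outer(L1, s1c) + outer(L2, s2) +
      matrix(rnorm(m * n, sd = GEN_NOISE_SD), m, n)
  }

  meta <- list(coupling = k, phase = phase, seed = as.integer(seed))

  # EOG: blink pulses plus attenuated neuronal leakage (makes the 12-Hz
  # low-pass of the ocular regression stage matter) plus sensor noise
  blink_sig <- numeric(n)
  blink_times <- integer(0)
  if (artifacts$blink && artifacts$blink_rate > 0) {
    n_ev <- rpois(1, artifacts$blink_rate * duration_s)
    if (n_ev > 0) {
      blink_times <- sort(sample.int(n - round(0.4 * rate), n_ev) +
                            round(0.2 * rate))
      pulse <- blink_pulse(rate)
      half <- length(pulse) %/% 2L
      for (b in blink_times) {
        i <- b:(b + length(pulse) - 1L) - half
        keep <- i >= 1L & i <= n
        blink_sig[i[keep]] <- blink_sig[i[keep]] + pulse[keep]
      }
    }
  }
  meta$blink_times <- blink_times
  amp_b <- artifacts$blink_amplitude
  eogh <- 0.7 * amp_b * blink_sig + 0.25 * s1_anterior + rnorm(n, sd = 0.1)
  eogv <- 1.0 * amp_b * blink_sig + 0.20 * s1_anterior + rnorm(n, sd = 0.1)
  X <- X + outer(BLINK_GAINS[EEG_CHANNELS], amp_b * blink_sig)

  # cardiac: jittered near-periodic Ricker spikes; the ECG channel carries the
  # same train at full amplitude
  ecg <- rnorm(n, sd = 0.2)
  r_times <- integer(0)
  if (artifacts$cardiac && artifacts$cardiac_rate > 0) {
    ivl <- rate / artifacts$cardiac_rate
    t0 <- ivl / 2
    while (t0 < n - rate %/% 8) {
      r_times <- c(r_times, round(t0))
      t0 <- t0 + ivl * (1 + 0.05 * runif(1, -1, 1))
    }
    tmpl <- cardiac_template(rate)
    train <- place_events(n, r_times, tmpl)
    ecg <- ecg + 25 * train
    gains <- artifacts$cardiac_amplitude * seq(1, 0.4, length.out = length(EEG_CHANNELS))
    X <- X + outer(gains, train)
  }
  meta$r_peaks <- r_times

  # muscle tension: band-limited noise above 15 Hz in the temporal channels
  if (artifacts$muscle) {
    h <- signal::fir1(128, artifacts$muscle_band / (rate / 2), "pass")
    mus <- function() {
      z <- apply_fir(rnorm(n), h)
      artifacts$muscle_amplitude * z / stats::sd(z)
    }
    X["T7", ] <- X["T7", ] + mus()
    X["T8", ] <- X["T8", ] + mus()
    X["F7", ] <- X["F7", ] + 0.5 * mus()
    X["F8", ] <- X["F8", ] + 0.5 * mus()
  }

  # slow drift below the high-pass edge, common to all channels with
  # channel-specific gains
  if (artifacts$drift) {
    h <- signal::fir1(512, max(artifacts$drift_band[2], 0.1) / (rate / 2), "low")
    d <- apply_fir(rnorm(n), h)
    d <- artifacts$drift_amplitude * d / stats::sd(d)
    gains <- 1 + 0.2 * sin(seq_along(EEG_CHANNELS))
    X <- X + outer(gains, d)
  }

  data <- rbind(X, EOGH = eogh, EOGV = eogv, ECG = ecg)
  eeg_recording(data, ALL_CHANNELS, rate, phase, meta = meta)
}
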