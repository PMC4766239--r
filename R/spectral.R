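# Lag-window multivariate spectral estimation.
#
# The spectral density is estimated indirectly: biased sample covariances up
# to a truncation lag are tapered with a Parzen window (which guarantees a
# positive-semidefinite estimate) and Fourier transformed,
#   f_hat(lambda) = (1/2pi) sum_{s=-c}^{c} w(s) gamma_hat(s) exp(-i lambda s).

#' Frequency bands of the analysis
#'
#' The band-limited (2-15 Hz) analysis uses four bands: delta 2-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, and beta0 13-15 Hz. Intervals are left-closed,
#' right-open, with the final band closed at 15 Hz.
#'
#' @return Named list of `c(low, high)` Hz intervals.
#' @export
frequency_bands <- function() {
  list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 13), beta0 = c(13, 15))
}

#' Biased multivariate sample covariance sequence
#'
#' Computes `gamma_hat(s) = (1/T) sum_t x(t+s) x(t)'` for lags `0..c` after
#' per-segment mean centering. The biased (1/T) normalization keeps the
#' sequence positive semidefinite, consistent with the Parzen-taper goal.
#' Multiple segments of equal length are pooled by averaging their covariance
#' sequences.
#'
#' @param x channels x samples matrix, a list of such matrices, or a
#'   [segment_set()].
#' @param max_lag maximum lag `c` (must be below the segment length).
#' @param method `"auto"` picks an FFT cross-correlation for large `max_lag`
#'   and direct products for small; `"direct"`/`"fft"` force a path.
#' @return Object of class `cov_seq`: list with `gamma` (n x n x (c+1) array),
#'   `n`, `max_lag`, `labels`, `nobs` (total pooled samples).
#' @export
sample_covariance <- function(x, max_lag, method = c("auto", "direct", "fft")) {
  method <- match.arg(method)
  segs <- if (inherits(x, "segment_set")) x$segments
          else if (is.list(x)) x else list(as.matrix(x))
  labels <- rownames(segs[[1]])
  n <- nrow(segs[[1]])
  Tlen <- ncol(segs[[1]])
  if (Tlen <= max_lag) stop("segment length must exceed `max_lag`")
  if (method == "auto") method <- if (max_lag > 32) "fft" else "direct"
  acc <- array(0, c(n, n, max_lag + 1L))
  for (X in segs) {
    X <- X - rowMeans(X)
    if (method == "direct") {
      for (s in 0:max_lag)
        acc[, , s + 1L] <- acc[, , s + 1L] +
          tcrossprod(X[, (1L + s):Tlen, drop = FALSE],
                     X[, 1L:(Tlen - s), drop = FALSE]) / Tlen
    } else {
      L <- stats::nextn(2L * Tlen, 2)
      F <- stats::mvfft(rbind(t(X), matrix(0, L - Tlen, n)))
      for (i in seq_len(n)) for (j in i:n) {
        r <- stats::fft(F[, i] * Conj(F[, j]), inverse = TRUE) / L
        acc[i, j, ] <- acc[i, j, ] + Re(r[1:(max_lag + 1L)]) / Tlen
        if (j > i) {
          # gamma_ji(s) corresponds to the negative lags of the same pair
          acc[j, i, ] <- acc[j, i, ] +
            Re(r[c(1L, L:(L - max_lag + 1L))]) / Tlen
        }
      }
    }
  }
  acc <- acc / length(segs)
  structure(list(gamma = acc, n = n, max_lag = max_lag, labels = labels,
                 nobs = Tlen * length(segs)),
            class = "cov_seq")
}

#' Parzen lag-window weight
#'
#' With `u = s/c`: `1 - 6u^2 + 6u^3` for `u <= 1/2`, `2(1-u)^3` for
#' `1/2 < u <= 1`, and 0 beyond the truncation point. The Parzen window is
#' non-negative definite, so the tapered spectral estimate is positive
#' semidefinite.
#'
#' @param s lag (vectorized, `s >= 0`).
#' @param c truncation point.
#' @return Weight(s) in \[0, 1\].
#' @export
parzen_weight <- function(s, c) {
  if (any(s < 0)) stop("lags must be non-negative")
  u <- s / c
  w <- ifelse(u <= 0.5, 1 - 6 * u^2 + 6 * u^3,
              ifelse(u <= 1, 2 * (1 - u)^3, 0))
  as.numeric(w)
}

#' Spectral configuration
#'
#' @param truncation Parzen truncation point `c` (default 255, the window
#'   closing optimum for 256-Hz band-limited EEG).
#' @param n_freq frequency-grid size on \[0, pi\] (default 1024, >= 2c).
#' @param window taper type; only `"parzen"` is provided.
#' @return List of class `spectral_config`.
#' @export
spectral_config <- function(truncation = 255, n_freq = 1024,
                            window = "parzen") {
  if (truncation < 1) stop("`truncation` must be >= 1")
  if (n_freq < 2 * truncation)
    stop("`n_freq` must be at least twice the truncation point")
  window <- match.arg(window, "parzen")
  structure(list(truncation = truncation, n_freq = n_freq, window = window),
            class = "spectral_config")
}

#' Parzen lag-window spectral density estimate
#'
#' Fourier transforms the tapered covariance sequence on an equispaced grid
#' of `n_freq` frequencies in \[0, pi\] (Hz mapping `f = lambda * rate / 2pi`).
#' The estimate is Hermitian at every frequency and positive semidefinite up
#' to round-off.
#'
#' @param cov a `cov_seq` from [sample_covariance()].
#' @param config a [spectral_config()]; `config$truncation` must not exceed
#'   `cov$max_lag`.
#' @param rate sampling rate in samples/s for the Hz mapping.
#' @return Object of class `spectral_estimate`: `f` (n x n x n_freq complex
#'   array), `freqs` (radians), `hz`, `rate`, `labels`.
#' @export
lag_window_spectrum <- function(cov, config = spectral_config(), rate = 256) {
  c0 <- config$truncation
  if (cov$max_lag < c0)
    stop("`cov$max_lag` (", cov$max_lag, ") is below the truncation point ", c0)
  n <- cov$n
  nf <- config$n_freq
  lam <- seq(0, pi, length.out = nf)
  w <- parzen_weight(1:c0, c0)
  G <- cov$gamma
  # vectorized over all channel pairs:
  # f_ij(l) = (1/2pi) [g_ij(0) + sum_s w_s ((g_ij(s)+g_ji(s)) cos(ls)
  #                                        - i (g_ij(s)-g_ji(s)) sin(ls))]
  Gs <- matrix(aperm(G[, , 2:(c0 + 1L), drop = FALSE], c(3, 1, 2)), c0, n * n)
  Gt <- matrix(aperm(aperm(G[, , 2:(c0 + 1L), drop = FALSE], c(2, 1, 3)),
                     c(3, 1, 2)), c0, n * n)
  CS <- cos(outer(lam, 1:c0))
  SN <- sin(outer(lam, 1:c0))
  RE <- (matrix(G[, , 1L], nf, n * n, byrow = TRUE) + CS %*% (w * (Gs + Gt))) / (2 * pi)
  IM <- -(SN %*% (w * (Gs - Gt))) / (2 * pi)
  FC <- matrix(complex(real = as.numeric(RE), imaginary = as.numeric(IM)),
               nf, n * n)
  f <- array(t(FC), c(n, n, nf))
  structure(list(f = f, freqs = lam, hz = lam * rate / (2 * pi), rate = rate,
                 labels = cov$labels),
            class = "spectral_estimate")
}

#' Construct a spectral estimate from an explicit array
#'
#' Wraps a complex Hermitian n x n x n_freq array (e.g. an analytic spectral
#' density evaluated on a grid) in the container the marker functions accept.
#'
#' @param f complex array, Hermitian at every frequency.
#' @param freqs radian frequency grid in \[0, pi\].
#' @param rate sampling rate for the Hz mapping.
#' @param labels optional channel labels.
#' @return A `spectral_estimate`.
#' @export
spectral_estimate <- function(f, freqs, rate = 256, labels = NULL) {
  stopifnot(length(dim(f)) == 3, dim(f)[1] == dim(f)[2],
            dim(f)[3] == length(freqs))
  structure(list(f = f, freqs = freqs, hz = freqs * rate / (2 * pi),
                 rate = rate, labels = labels),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d x %d, %d frequencies in [0, %.3g] rad (0-%.4g Hz)\n",
              dim(x$f)[1], dim(x$f)[2], length(x$freqs), max(x$freqs), max(x$hz)))
  invisible(x)
}

#' Per-frequency inverse of a spectral density estimate
#'
#' Inverts `f(lambda)` at every grid frequency; ill-conditioned frequencies
#' (condition number above 1e10) are ridge-regularized by
#' `delta * trace/n * I` with `delta = 1e-8`, with a warning.
#'
#' @param spec a `spectral_estimate`.
#' @return A `spectral_estimate` holding `g = f^{-1}`.
#' @export
inverse_spectrum <- function(spec) {
  n <- dim(spec$f)[1]
  nf <- dim(spec$f)[3]
  g <- array(complex(real = 0), dim(spec$f))
  ridged <- FALSE
  I_n <- diag(n)
  for (m in seq_len(nf)) {
    fm <- spec$f[, , m, drop = TRUE]
    if (n == 1L) fm <- matrix(fm, 1, 1)
    if (rcond(fm) < 1e-10) {
      fm <- fm + 1e-8 * Re(sum(diag(fm))) / n * I_n
      ridged <- TRUE
    }
    g[, , m] <- solve(fm)
  }
  if (ridged)
    warning("ill-conditioned spectral matrix: ridge regularization applied at some frequencies")
  out <- spec
  out$f <- g
  out$inverse <- TRUE
  out
}

#' Average per-frequency values over a frequency band
#'
#' Arithmetic mean over the grid frequencies whose Hz value falls in
#' `[low, high)`; the 13-15 Hz band is closed at 15 Hz so the band edges tile
#' the full 2-15 Hz analysis range.
#'
#' @param values numeric vector, one value per grid frequency.
#' @param band band name (see [frequency_bands()]) or a `c(low, high)` Hz pair.
#' @param hz Hz value of each grid frequency.
#' @return Scalar band average.
#' @export
band_average <- function(values, band, hz) {
  if (is.character(band)) {
    bands <- frequency_bands()
    if (!band %in% names(bands)) stop("unknown band: ", band)
    iv <- bands[[band]]
    closed <- band == "beta0"
  } else {
    iv <- band
    closed <- abs(iv[2] - 15) < 1e-9
  }
  sel <- hz >= iv[1] & (if (closed) hz <= iv[2] else hz < iv[2])
  if (!any(sel)) stop("frequency grid has no points in band [",
                      iv[1], ", ", iv[2], ")")
  mean(values[sel])
}

#' Fit a vector autoregression by Yule-Walker with AIC order selection
#'
#' Solves the multivariate Yule-Walker equations from the pooled biased
#' covariance sequence for every candidate order `p <= max_order` and returns
#' the AIC-minimizing stable model. AIC is the standard multivariate form
#' `T log det(Sigma) + 2 p n^2`.
#'
#' @param x segments (matrix, list of matrices, or [segment_set()]).
#' @param max_order maximum candidate order (>= 1).
#' @return Object of class `ar_model`: `order`, `A` (n x n x p coefficient
#'   array of the VAR form `x(t) = sum A(s) x(t-s) + e(t)`), `sigma`
#'   (innovation covariance), `aic`, `labels`.
#' @export
fit_ar <- function(x, max_order = 10) {
  if (max_order < 1) stop("`max_order` must be >= 1")
  cov <- if (inherits(x, "cov_seq")) x else sample_covariance(x, max_order)
  if (cov$max_lag < max_order) stop("covariance sequence too short for `max_order`")
  n <- cov$n
  Tn <- cov$nobs
  G <- cov$gamma
  gblock <- function(s) if (s >= 0) G[, , s + 1L] else t(G[, , -s + 1L])
  best <- NULL
  for (p in seq_len(max_order)) {
    Gm <- matrix(0, n * p, n * p)
    Cm <- matrix(0, n, n * p)
    for (s in 1:p) {
      Cm[, ((s - 1) * n + 1):(s * n)] <- gblock(s)
      for (u in 1:p)
        Gm[((s - 1) * n + 1):(s * n), ((u - 1) * n + 1):(u * n)] <- gblock(u - s)
    }
    B <- tryCatch(t(solve(Gm, t(Cm))), error = function(e)
      stop("singular Yule-Walker system at order ", p,
           " (duplicated or linearly dependent channels?)"))
    A <- array(B, c(n, n, p))
    Sig <- gblock(0)
    for (s in 1:p) Sig <- Sig - A[, , s] %*% t(gblock(s))
    Sig <- (Sig + t(Sig)) / 2
    dS <- det(Sig)
    if (!is.finite(dS) || dS <= 0) next
    aic <- Tn * log(dS) + 2 * p * n^2
    # companion-matrix stability
    comp <- matrix(0, n * p, n * p)
    comp[1:n, ] <- B
    if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
    stable <- max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
    if (stable && (is.null(best) || aic < best$aic))
      best <- list(order = p, A = A, sigma = Sig, aic = aic)
  }
  if (is.null(best)) stop("no stable Yule-Walker fit up to order ", max_order)
  structure(c(best, list(labels = cov$labels, nobs = Tn)), class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> VAR(%d) on %d channels, AIC = %.2f\n",
              x$order, nrow(x$sigma), x$aic))
  invisible(x)
}
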