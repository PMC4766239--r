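# The eight synchrony markers.
#
# Frequency-domain markers (coherence, partial coherence, phase shift,
# dynamic canonical correlation) are evaluated per grid frequency and
# averaged within the delta/theta/alpha/beta0 bands; time-domain markers
# (Granger causality, conditional Granger causality, static canonical
# correlation, cross-mutual information) are computed from covariances, AR
# fits or joint histograms.

spec_index <- function(spec, ch) {
  if (is.character(ch)) {
    i <- match(ch, spec$labels)
    if (is.na(i)) stop("unknown channel: ", ch)
    i
  } else as.integer(ch)
}

#' Coherence between two channels
#'
#' `C_ij(lambda) = |f_ij|^2 / (f_ii f_jj)`, band-averaged. Symmetric in
#' (i, j), in \[0, 1\], blind to the direction of influence.
#'
#' @param spec a `spectral_estimate`.
#' @param i,j channel indices or labels.
#' @param band band name or Hz interval; `NULL` returns the per-frequency
#'   curve.
#' @return Band-averaged coherence (or the full curve).
#' @export
coherence <- function(spec, i, j, band = NULL) {
  i <- spec_index(spec, i); j <- spec_index(spec, j)
  fii <- Re(spec$f[i, i, ]); fjj <- Re(spec$f[j, j, ])
  num <- Mod(spec$f[i, j, ])^2
  den <- fii * fjj
  C <- rep(NA_real_, length(den))
  ok <- den > 0
  if (!all(ok)) warning("zero auto-spectrum at some frequencies: skipped")
  C[ok] <- pmin(num[ok] / den[ok], 1)
  if (is.null(band)) return(C)
  band_average_ok(C, band, spec$hz)
}

# band average ignoring skipped (NA) frequencies; errors if the whole band
# was skipped
band_average_ok <- function(values, band, hz) {
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
  v <- values[sel]
  if (all(is.na(v))) stop("all band frequencies were skipped")
  mean(v, na.rm = TRUE)
}

#' Partial coherence between two channels
#'
#' `pC_ij(lambda) = |g_ij|^2 / (g_ii g_jj)` with `g = f^{-1}`: the coherence
#' remaining after linearly removing all other channels in the spectral
#' matrix. Symmetric; for n = 2 it coincides with ordinary coherence.
#'
#' @param spec a `spectral_estimate` of the *full* channel set.
#' @param i,j channel indices or labels.
#' @param band band name or Hz interval; `NULL` for the curve.
#' @param ginv optionally, a precomputed [inverse_spectrum()].
#' @return Band-averaged partial coherence.
#' @export
partial_coherence <- function(spec, i, j, band = NULL, ginv = NULL) {
  if (is.null(ginv)) ginv <- inverse_spectrum(spec)
  coherence(ginv, i, j, band)
}

#' Normalized phase shift between two channels
#'
#' Writes the cross-spectrum in polar form `f_ij = |f_ij| exp(i Phi_ij)` and
#' averages `|Phi_ij| / pi` (principal value, no unwrapping) over the band.
#' Values lie in \[0, 1\]; frequencies with a vanishing cross-spectrum are
#' skipped with a warning.
#'
#' @inheritParams coherence
#' @return Band-averaged normalized phase.
#' @export
phase_shift <- function(spec, i, j, band = NULL) {
  i <- spec_index(spec, i); j <- spec_index(spec, j)
  fij <- spec$f[i, j, ]
  nphi <- abs(Arg(fij)) / pi
  zero <- Mod(fij) == 0
  if (any(zero)) {
    warning("vanishing cross-spectrum at some frequencies: skipped")
    nphi[zero] <- NA_real_
  }
  if (i == j) nphi[] <- 0
  if (is.null(band)) return(nphi)
  band_average_ok(nphi, band, spec$hz)
}

#' Bivariate Granger causality
#'
#' Fits a bivariate AR model to the pooled segments of channels `x` and `y`
#' by Yule-Walker with AIC order selection and returns the Euclidean norm of
#' the cross-coefficient path: `G(x -> y) = sqrt(sum_s A_yx(s)^2)` where
#' `A_yx(s)` predicts `y(t)` from `x(t-s)`. Zero coefficients for all lags
#' are equivalent to Granger non-causality.
#'
#' @param x,y single-channel segments: numeric vectors, lists of vectors, or
#'   1 x T matrices/lists thereof.
#' @param max_order maximum AR order offered to AIC (default 10).
#' @return List with `forward` (x -> y), `backward` (y -> x) and `order`.
#' @export
granger <- function(x, y, max_order = 10) {
  xs <- if (is.list(x)) x else list(x)
  ys <- if (is.list(y)) y else list(y)
  segs <- mapply(function(a, b) rbind(x = as.numeric(a), y = as.numeric(b)),
                 xs, ys, SIMPLIFY = FALSE)
  fit <- fit_ar(segs, max_order = max_order)
  list(forward = sqrt(sum(fit$A[2, 1, ]^2)),
       backward = sqrt(sum(fit$A[1, 2, ]^2)),
       order = fit$order)
}

#' Conditional Granger causality
#'
#' Euclidean norm of the (j, i) coefficient path of the *full* n-variate AR
#' model, so the influence of `i` on `j` is assessed conditionally on all
#' remaining channels.
#'
#' @param x n-channel segments (matrix, list of matrices, [segment_set()], or
#'   a prefitted `ar_model`).
#' @param i,j source and target channel (index or label).
#' @param max_order maximum AR order offered to AIC.
#' @return List with `value` (cG of i -> j), `reverse` (j -> i) and `order`.
#' @export
conditional_granger <- function(x, i, j, max_order = 10) {
  fit <- if (inherits(x, "ar_model")) x else fit_ar(x, max_order = max_order)
  li <- if (is.character(i)) match(i, fit$labels) else as.integer(i)
  lj <- if (is.character(j)) match(j, fit$labels) else as.integer(j)
  if (is.na(li) || is.na(lj)) stop("unknown channel in conditional_granger()")
  list(value = sqrt(sum(fit$A[lj, li, ]^2)),
       reverse = sqrt(sum(fit$A[li, lj, ]^2)),
       order = fit$order)
}

# Hermitian square-root inverse via eigendecomposition, with ridge fallback
herm_sqrt_inv <- function(M, ridge = 1e-8) {
  M <- (M + Conj(t(M))) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < max(vals) * 1e-10) {
    warning("singular block: ridge regularization applied")
    vals <- vals + ridge * max(max(vals), 1)
  }
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% Conj(t(e$vectors))
}

#' Static canonical correlation between two channel blocks
#'
#' The canonical correlations are the square roots of the eigenvalues of
#' `g_II^{-1/2} g_IJ g_JJ^{-1} g_JI g_II^{-1/2}` built from the lag-0
#' covariance. The marker value is the Euclidean norm of the coefficients.
#'
#' @param gamma0 lag-0 covariance matrix of all channels (or a `cov_seq`).
#' @param I,J disjoint index vectors (or label vectors) of the two blocks.
#' @return List of class `canonical_result`: `rho` (descending, clipped to
#'   \[0, 1\]), `norm`, `r`.
#' @export
canonical_corr <- function(gamma0, I, J) {
  G <- if (inherits(gamma0, "cov_seq")) gamma0$gamma[, , 1] else as.matrix(gamma0)
  labels <- if (inherits(gamma0, "cov_seq")) gamma0$labels else rownames(G)
  if (is.character(I)) I <- match(I, labels)
  if (is.character(J)) J <- match(J, labels)
  if (length(intersect(I, J))) stop("`I` and `J` must be disjoint")
  rho <- cancor_rho(G[I, I, drop = FALSE], G[J, J, drop = FALSE],
                    G[I, J, drop = FALSE])
  structure(list(rho = rho, norm = sqrt(sum(rho^2)), r = length(rho)),
            class = "canonical_result")
}

cancor_rho <- function(SII, SJJ, SIJ) {
  Wi <- herm_sqrt_inv(SII)
  M <- Wi %*% SIJ %*% solve(SJJ) %*% Conj(t(SIJ)) %*% Conj(t(Wi))
  M <- (M + Conj(t(M))) / 2
  ev <- Re(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  r <- min(nrow(SII), nrow(SJJ))
  rho2 <- sort(ev, decreasing = TRUE)[seq_len(r)]
  sqrt(pmin(pmax(rho2, 0), 1))
}

#' Dynamic canonical correlation between two channel blocks
#'
#' Frequency-domain generalization: per frequency, the square roots of the
#' eigenvalues of `f_II^{-1/2} f_IJ f_JJ^{-1} f_JI f_II^{-1/2}`, allowing
#' filtered (lagged) linear combinations. The per-frequency Euclidean norm of
#' the coefficients is band-averaged.
#'
#' @param spec a `spectral_estimate` covering both blocks.
#' @param I,J disjoint index/label vectors.
#' @param band band name or Hz interval; `NULL` returns the per-frequency
#'   norm curve.
#' @return Band-averaged norm of the dynamic canonical correlations.
#' @export
dynamic_canonical_corr <- function(spec, I, J, band = NULL) {
  if (is.character(I)) I <- match(I, spec$labels)
  if (is.character(J)) J <- match(J, spec$labels)
  if (length(intersect(I, J))) stop("`I` and `J` must be disjoint")
  nf <- dim(spec$f)[3]
  norms <- vapply(seq_len(nf), function(m) {
    fm <- spec$f[, , m]
    rho <- cancor_rho(fm[I, I, drop = FALSE], fm[J, J, drop = FALSE],
                      fm[I, J, drop = FALSE])
    sqrt(sum(rho^2))
  }, numeric(1))
  if (is.null(band)) return(norms)
  band_average_ok(norms, band, spec$hz)
}

#' Normalized cross-mutual information
#'
#' Estimates the mutual information of two series from a 10 x 10 joint
#' histogram with equiprobable (decile) marginal bins and normalizes it as
#' `2 I / (H_X + H_Y)`, which lies in \[0, 1\] and equals 1 for `y = x`.
#' The convention `0 log 0 = 0` applies.
#'
#' @param x,y numeric series of equal length (>= 100).
#' @param bins marginal bin count (default 10).
#' @param normalization `"maes"` for `2I/(H_X+H_Y)` (default) or `"max"` for
#'   `I/max(H_X, H_Y)`.
#' @return Normalized cross-mutual information in \[0, 1\].
#' @export
cross_mutual_info <- function(x, y, bins = 10,
                              normalization = c("maes", "max")) {
  normalization <- match.arg(normalization)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 100) stop("series too short (need >= 100 samples)")
  edges <- function(v) {
    e <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                         names = FALSE, type = 7)
    e <- unique(e)
    if (length(e) < 2) stop("constant input: histogram bins are undefined")
    e[1] <- -Inf; e[length(e)] <- Inf
    e
  }
  cx <- cut(x, edges(x), labels = FALSE, include.lowest = TRUE)
  cy <- cut(y, edges(y), labels = FALSE, include.lowest = TRUE)
  counts <- table(cx, cy)
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  I <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  Hx <- -sum(px[px > 0] * log2(px[px > 0]))
  Hy <- -sum(py[py > 0] * log2(py[py > 0]))
  v <- switch(normalization,
              maes = 2 * I / (Hx + Hy),
              max = I / max(Hx, Hy))
  min(max(v, 0), 1)
}

#' Joint histogram with equiprobable marginals
#'
#' The 10 x 10 binning underlying [cross_mutual_info()], exposed for
#' inspection.
#'
#' @inheritParams cross_mutual_info
#' @return List with `counts`, `edges_x`, `edges_y`, `total`.
#' @export
joint_histogram <- function(x, y, bins = 10) {
  e <- function(v) {
    q <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                         names = FALSE, type = 7)
    q <- unique(q)
    if (length(q) < 2) stop("constant input: histogram bins are undefined")
    q
  }
  ex <- e(x); ey <- e(y)
  cx <- cut(x, ex, labels = FALSE, include.lowest = TRUE)
  cy <- cut(y, ey, labels = FALSE, include.lowest = TRUE)
  counts <- table(factor(cx, seq_len(length(ex) - 1)),
                  factor(cy, seq_len(length(ey) - 1)))
  list(counts = unclass(counts), edges_x = ex, edges_y = ey,
       total = length(x))
}
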