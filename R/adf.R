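# Augmented Dickey-Fuller unit-root test (constant, no trend).
#
# Regression:  diff(x)_t = c + rho * x_{t-1} + sum_j b_j diff(x)_{t-j} + e_t
# The lag order is chosen by AIC up to `max_lag` on a common sample (trimmed
# at the maximum lag) using the nested-model residual sums of squares of a
# single QR factorization. The test statistic rho_hat / se(rho_hat) is
# compared with MacKinnon (2010) response-surface critical values.

# response-surface coefficients for the constant-only case, levels 1/5/10 %
MACKINNON_TAU_C <- rbind(
  `0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
  `0.05` = c(-2.86154, -2.8903,  -4.234, -40.040),
  `0.10` = c(-2.56677, -1.5384,  -2.809,   0.000)
)

adf_critical <- function(n, level = 0.05) {
  key <- sprintf("%.2f", level)
  if (!key %in% rownames(MACKINNON_TAU_C))
    stop("ADF critical values available at levels 0.01, 0.05, 0.10 only")
  b <- MACKINNON_TAU_C[key, ]
  b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3
}

#' Augmented Dickey-Fuller stationarity check
#'
#' Tests the unit-root null against a (level-)stationary alternative on a
#' single-channel segment; the regression includes a constant and AIC-selected
#' lagged differences. The segment is flagged stationary when the null is
#' rejected at `level`.
#'
#' @param x numeric series (>= 50 samples).
#' @param max_lag maximum augmentation lag considered by AIC (default 10).
#' @param level test level; 0.01, 0.05 or 0.10 (default 0.05).
#' @return List with `statistic` (tau), `critical`, `lag` (selected), and
#'   `stationary` (logical: null rejected).
#' @export
adf_stationary <- function(x, max_lag = 10, level = 0.05) {
  n <- length(x)
  if (n < 50) stop("series too short for the ADF test (need >= 50 samples)")
  if (stats::sd(x) == 0) stop("constant series: ADF regression is degenerate")
  dx <- diff(x)
  k <- min(max_lag, n %/% 4L)
  # common sample: t = k+2 .. n (response diff x_t), trimmed at max lag
  emb <- stats::embed(dx, k + 1L)            # [dx_t, dx_{t-1}, ..., dx_{t-k}]
  y <- emb[, 1L]
  lev <- x[(k + 1L):(n - 1L)]                # x_{t-1}
  Z <- cbind(const = 1, level = lev,
             if (k > 0) emb[, -1L, drop = FALSE])
  Te <- length(y)
  p <- ncol(Z)
  # Cholesky of the augmented cross-product gives the nested-model residual
  # sums of squares in one pass: for the model using the first m columns,
  # RSS_m = Ra[p+1, p+1]^2 + sum(Ra[(m+1):p, p+1]^2)
  Ra <- tryCatch(chol(crossprod(cbind(Z, y))), error = function(e)
    stop("degenerate ADF regression (collinear design)"))
  qty <- Ra[seq_len(p), p + 1L]
  rss_full <- Ra[p + 1L, p + 1L]^2
  rss_tail <- rev(cumsum(rev(qty^2)))
  rss_m <- function(m) rss_full + if (m < p) rss_tail[m + 1L] else 0
  aic <- vapply(0:k, function(j) {
    m <- 2L + j
    Te * log(rss_m(m) / Te) + 2 * (m + 1)
  }, numeric(1))
  j <- which.min(aic) - 1L
  m <- 2L + j
  R <- Ra[seq_len(m), seq_len(m), drop = FALSE]
  b <- backsolve(R, qty[seq_len(m)])
  rss <- rss_m(m)
  Rinv <- backsolve(R, diag(m))
  se <- sqrt(rowSums(Rinv^2) * rss / (Te - m))
  stat <- b[2L] / se[2L]
  crit <- adf_critical(Te, level)
  list(statistic = unname(stat), critical = unname(crit),
       lag = j, stationary = unname(stat < crit))
}
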