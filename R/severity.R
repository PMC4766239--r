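# Marker-versus-severity statistics.
#
# Quadratic OLS of each marker on MMSE with demographic covariates (age, sex,
# AD duration, education; age and duration also quadratic), overall F-test
# with Bonferroni control over the eight-marker family, Mann-Whitney
# comparison of the two MMSE regimes, and marker correlation matrices.

#' Quadratic severity regression
#'
#' Fits `y ~ mmse + mmse^2 + age + age^2 + sex + duration + duration^2 +
#' education` by OLS. MMSE, age and duration are mean-centered before
#' squaring to reduce collinearity (R^2 and the F-test are invariant to
#' this). The overall F-test compares the full model with the intercept-only
#' model.
#'
#' @param y numeric response, one value per cohort row (a marker or factor
#'   score).
#' @param cohort data.frame with columns `mmse`, `age`, `sex`, `education`,
#'   `ad_duration`.
#' @param covariates include the demographic covariates (default TRUE); with
#'   FALSE only the MMSE terms enter.
#' @return List of class `severity_fit`: `coefficients`, `r_squared`,
#'   `f_pvalue`, `f_statistic`, `df`, `n`, `vertex` (MMSE at the fitted
#'   quadratic extremum), `mmse_coef` (linear and quadratic MMSE
#'   coefficients, centered parameterization), `r_squared_mmse_partial`
#'   (partial R^2 of the MMSE terms given the covariates).
#' @export
quadratic_regression <- function(y, cohort, covariates = TRUE) {
  n <- length(y)
  if (n != nrow(cohort)) stop("`y` must have one value per cohort row")
  if (n < 12) stop("need at least 12 observations for the nine-parameter model")
  mm <- cohort$mmse - mean(cohort$mmse)
  ag <- cohort$age - mean(cohort$age)
  du <- cohort$ad_duration - mean(cohort$ad_duration)
  sx <- as.numeric(factor(cohort$sex)) - 1
  ed <- as.numeric(cohort$education)
  dat <- data.frame(y = y, mmse = mm, mmse2 = mm^2)
  form <- y ~ mmse + mmse2
  if (covariates) {
    dat <- cbind(dat, age = ag, age2 = ag^2, sex = sx,
                 duration = du, duration2 = du^2, education = ed)
    form <- y ~ mmse + mmse2 + age + age2 + sex + duration + duration2 + education
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design: collinear columns dropped")
  }
  sm <- summary(fit)
  fs <- sm$fstatistic
  f_p <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  b <- stats::coef(fit)
  b1 <- unname(b["mmse"]); b2 <- unname(b["mmse2"])
  vertex <- if (is.finite(b2) && b2 != 0) mean(cohort$mmse) - b1 / (2 * b2)
            else NA_real_
  # partial R^2 of the MMSE terms given the covariates
  r2_part <- NA_real_
  if (covariates) {
    red <- stats::lm(y ~ age + age2 + sex + duration + duration2 + education,
                     data = dat)
    rss_f <- sum(stats::residuals(fit)^2)
    rss_r <- sum(stats::residuals(red)^2)
    r2_part <- if (rss_r > 0) (rss_r - rss_f) / rss_r else NA_real_
  }
  structure(list(coefficients = b, r_squared = sm$r.squared,
                 f_pvalue = unname(f_p),
                 f_statistic = if (is.null(fs)) NA_real_ else unname(fs[1]),
                 df = if (is.null(fs)) c(NA, NA) else unname(fs[2:3]),
                 n = n, vertex = vertex, mmse_coef = c(linear = b1, quadratic = b2),
                 r_squared_mmse_partial = r2_part),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("<severity_fit> n = %d, R^2 = %.3f, F p = %.4g, vertex at MMSE %.2f\n",
              x$n, x$r_squared, x$f_pvalue, x$vertex))
  invisible(x)
}

#' Bonferroni significance flags
#'
#' Controls the family-wise error rate over a family of `m` markers by the
#' strict threshold `p < 0.05 / m` (0.00625 for the eight-marker family).
#'
#' @param p_values numeric p-values.
#' @param m family size (default 8).
#' @param alpha family-wise level (default 0.05).
#' @return Logical flags, with the threshold attached as attribute
#'   `"threshold"`.
#' @export
bonferroni_flags <- function(p_values, m = 8, alpha = 0.05) {
  if (m < 1) stop("`m` must be >= 1")
  thr <- alpha / m
  structure(p_values < thr, threshold = thr)
}

#' Mann-Whitney comparison of two MMSE regimes
#'
#' Splits the cohort at an MMSE threshold (group A: `mmse >= cut`, group B:
#' `mmse < cut`, default 21) and tests equality of distributions of `y` by a
#' two-sided Mann-Whitney U test — exact when the combined sample is at most
#' 20 and tie-free, otherwise by the tie-corrected normal approximation.
#'
#' @param y numeric values, one per cohort row.
#' @param cohort cohort data.frame with an `mmse` column.
#' @param cut MMSE regime boundary (default 21; the boundary value falls in
#'   the upper group).
#' @return List with `u` (U statistic of the upper group), `p_value`,
#'   `n_upper`, `n_lower`.
#' @export
mmse_regime_test <- function(y, cohort, cut = 21) {
  upper <- y[cohort$mmse >= cut]
  lower <- y[cohort$mmse < cut]
  if (!length(upper) || !length(lower))
    stop("both MMSE regimes must be non-empty (cut = ", cut, ")")
  if (stats::sd(c(upper, lower)) == 0) {
    # all values tied: no evidence against equal medians
    return(list(u = length(upper) * length(lower) / 2, p_value = 1,
                n_upper = length(upper), n_lower = length(lower)))
  }
  ties <- anyDuplicated(c(upper, lower)) > 0
  exact <- (length(upper) + length(lower) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(upper, lower, exact = exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_upper = length(upper), n_lower = length(lower))
}

#' Pearson correlations between markers
#'
#' Correlation matrix of marker values across subjects, e.g. for one cluster
#' pair and phase. Zero-variance markers yield NA entries with a warning.
#'
#' @param x subjects x markers numeric matrix or data.frame.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
marker_correlations <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance marker(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            " — correlations reported as NA")
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}
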