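# Common-factor analysis of the synchrony markers.
#
# Maximum-likelihood factor extraction on the marker correlation matrix with
# an oblique promax rotation; factor scores by the regression (Thomson)
# method; factor scores are then related to severity by the same quadratic
# regression used for the individual markers.

#' Maximum-likelihood common factors with oblique rotation
#'
#' Extracts `n_factors` common factors from the standardized marker matrix by
#' maximum likelihood and rotates them obliquely (promax). Factor
#' correlations are recovered from the rotation matrix, structure loadings as
#' `pattern %*% phi`, and regression-method scores as
#' `Z R^{-1} (pattern %*% phi)`. Factor signs are fixed so each pattern
#' column sums non-negative.
#'
#' @param x subjects x markers matrix or data.frame (subjects >= markers).
#' @param n_factors number of common factors (default 2).
#' @param max_iter iteration cap passed to the ML optimizer.
#' @return List of class `factor_model`: `loadings` (pattern matrix),
#'   `structure`, `phi` (factor correlation matrix), `scores`,
#'   `uniquenesses`, `n_factors`, `rotation`.
#' @export
factor_analysis <- function(x, n_factors = 2, max_iter = 1000) {
  x <- as.matrix(x)
  p <- ncol(x); n <- nrow(x)
  if (n < p) stop("need at least as many subjects as markers")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance marker column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  Z <- scale(x)
  fa <- tryCatch(
    stats::factanal(Z, factors = n_factors, rotation = "none",
                    control = list(nstart = 3, opt = list(maxit = max_iter),
                                   lower = 0.005)),
    error = function(e) stop("factor extraction failed: ", conditionMessage(e)))
  L <- unclass(fa$loadings)
  if (any(1 - fa$uniquenesses >= 0.995))
    warning("Heywood case: communality bounded at 0.995")
  if (n_factors > 1) {
    pm <- stats::promax(L)
    Lr <- unclass(pm$loadings)
    phi <- stats::cov2cor(solve(crossprod(pm$rotmat)))
  } else {
    Lr <- L
    phi <- matrix(1, 1, 1)
  }
  # sign convention: each factor's pattern loadings sum non-negative
  sgn <- ifelse(colSums(Lr) < 0, -1, 1)
  Lr <- sweep(Lr, 2, sgn, `*`)
  phi <- diag(sgn, n_factors) %*% phi %*% diag(sgn, n_factors)
  S <- Lr %*% phi                       # structure matrix
  R <- stats::cor(x)
  scores <- Z %*% solve(R, S)           # Thomson regression scores
  colnames(scores) <- colnames(S) <- colnames(Lr) <-
    paste0("F", seq_len(n_factors))
  rownames(scores) <- rownames(x)
  structure(list(loadings = Lr, structure = S, phi = phi, scores = scores,
                 uniquenesses = fa$uniquenesses, n_factors = n_factors,
                 rotation = if (n_factors > 1) "promax" else "none"),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors (%s rotation), %d markers, %d subjects\n",
              x$n_factors, x$rotation, nrow(x$loadings), nrow(x$scores)))
  if (x$n_factors > 1)
    cat(sprintf("  factor correlation (F1, F2): %.3f\n", x$phi[1, 2]))
  invisible(x)
}

#' Sequential likelihood-ratio choice of the factor count
#'
#' Fits 1, 2, ... factors by maximum likelihood and returns the smallest
#' count whose goodness-of-fit test is not rejected.
#'
#' @param x subjects x markers matrix.
#' @param max_factors largest count to consider.
#' @param level test level (default 0.05).
#' @return Integer factor count, with the per-count p-values as attribute.
#' @export
choose_n_factors <- function(x, max_factors = 3, level = 0.05) {
  x <- as.matrix(x)
  pv <- vapply(seq_len(max_factors), function(k) {
    fa <- tryCatch(stats::factanal(scale(x), factors = k, rotation = "none"),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fa$PVAL)) NA_real_ else unname(fa$PVAL)
  }, numeric(1))
  k <- which(pv > level)[1]
  if (is.na(k)) k <- max_factors
  structure(as.integer(k), p_values = pv)
}

#' Severity regression of factor scores
#'
#' Applies [quadratic_regression()] to each factor's scores.
#'
#' @param model a [factor_analysis()] result whose scores have one row per
#'   cohort row.
#' @param cohort cohort data.frame.
#' @param ... passed to [quadratic_regression()].
#' @return Named list of `severity_fit` objects, one per factor.
#' @export
factor_regression <- function(model, cohort, ...) {
  if (nrow(model$scores) != nrow(cohort))
    stop("factor scores and cohort differ in size")
  out <- lapply(seq_len(model$n_factors), function(k)
    quadratic_regression(model$scores[, k], cohort, ...))
  names(out) <- colnames(model$scores)
  out
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence after optimal column matching and sign alignment;
#' used to compare recovered loadings with a known structure.
#'
#' @param A,B loadings matrices with the same number of rows.
#' @return Numeric vector, one congruence value per column of `A`.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  cong <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  # match each column of A to its best column of B (greedy)
  avail <- seq_len(ncol(B))
  out <- numeric(ncol(A))
  for (k in seq_len(ncol(A))) {
    cs <- vapply(avail, function(j) cong(A[, k], B[, j]), numeric(1))
    j <- which.max(cs)
    out[k] <- cs[j]
    avail <- avail[-j]
  }
  out
}
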