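# Covariance sequences, Parzen lag-window spectra, AR fits

test_that("sample covariance matches its defining moments", {
  set.seed(1)
  T <- 20000
  X <- matrix(rnorm(2 * T), 2)
  cv <- sample_covariance(X, 10)
  expect_equal(cv$gamma[, , 1], diag(2), tolerance = 0.05)
  expect_lt(max(abs(cv$gamma[, , 2:11])), 0.05)
  # zero signal
  z <- sample_covariance(matrix(0, 2, 100), 5)
  expect_true(all(z$gamma == 0))
  # lagged copy: gamma_21(1) ~ var(x1), gamma_21(0) ~ 0
  x1 <- rnorm(T + 1)
  Y <- rbind(x1 = x1[2:(T + 1)], x2 = x1[1:T])
  cvy <- sample_covariance(Y, 3)
  expect_equal(cvy$gamma[2, 1, 2], 1, tolerance = 0.05)
  expect_lt(abs(cvy$gamma[2, 1, 1]), 0.05)
  expect_error(sample_covariance(matrix(rnorm(20), 2), 15), "exceed")
})

test_that("FFT and direct covariance paths agree to machine precision", {
  set.seed(2)
  X <- matrix(rnorm(3 * 700), 3)
  a <- sample_covariance(X, 64, method = "direct")
  b <- sample_covariance(X, 64, method = "fft")
  expect_equal(a$gamma, b$gamma, tolerance = 1e-12)
})

test_that("Parzen weights take their closed-form values", {
  expect_equal(parzen_weight(0, 256), 1)
  expect_equal(parzen_weight(256, 256), 0)
  expect_equal(parzen_weight(128, 256), 0.25)  # both branches meet at u = 1/2
  expect_equal(parzen_weight(300, 256), 0)     # beyond truncation: zero
  w <- parzen_weight(0:256, 256)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(parzen_weight(-1, 256), "non-negative")
})

test_that("lag-window spectrum matches closed forms and integral identity", {
  set.seed(4)
  T <- 46080
  X <- matrix(rnorm(2 * T), 2)
  X[2, ] <- 0.5 * X[2, ] + 0.3 * X[1, ]
  cv <- sample_covariance(X, 255)
  sp <- lag_window_spectrum(cv, spectral_config())
  # white noise: flat at Sigma / 2pi (up to sampling scatter of the taper)
  target <- cv$gamma[1, 1, 1] / (2 * pi)
  expect_lt(mean(abs(Re(sp$f[1, 1, ]) - target)) / target, 0.1)
  expect_lt(max(abs(Re(sp$f[1, 1, ]) - target)) / target, 0.5)
  # inverse-transform identity at lag 0
  expect_equal(mean(Re(sp$f[1, 1, ])) * 2 * pi, cv$gamma[1, 1, 1],
               tolerance = 0.01)
  expect_equal(mean(Re(sp$f[2, 2, ])) * 2 * pi, cv$gamma[2, 2, 1],
               tolerance = 0.01)
  # scalar AR(1) with coefficient 0.5: within 10 % at band centers
  ar1 <- as.numeric(stats::filter(rnorm(T), 0.5, method = "recursive"))
  sp1 <- lag_window_spectrum(sample_covariance(matrix(ar1, 1), 255),
                             spectral_config())
  truth <- function(l) 1 / (2 * pi * Mod(1 - 0.5 * exp(-1i * l))^2)
  for (b in names(frequency_bands())) {
    ctr <- mean(frequency_bands()[[b]])
    est <- Re(sp1$f[1, 1, which.min(abs(sp1$hz - ctr))])
    expect_lt(abs(est - truth(2 * pi * ctr / 256)) / truth(2 * pi * ctr / 256),
              0.1)
  }
})

test_that("spectral estimates are Hermitian and positive semidefinite", {
  set.seed(6)
  for (trial in 1:25) {
    n <- sample(2:4, 1)
    X <- matrix(rnorm(n * 400), n)
    if (trial %% 2 == 0)
      X <- X + matrix(as.numeric(stats::filter(rnorm(400), 0.8,
                                               method = "recursive")),
                      n, 400, byrow = TRUE)
    sp <- lag_window_spectrum(sample_covariance(X, 64),
                              spectral_config(64, 256))
    herm <- max(vapply(seq_len(dim(sp$f)[3]), function(m)
      max(Mod(sp$f[, , m] - Conj(t(sp$f[, , m])))), numeric(1)))
    expect_lt(herm, 1e-10)
    mins <- vapply(seq_len(dim(sp$f)[3]), function(m)
      min(Re(eigen(sp$f[, , m], symmetric = FALSE,
                   only.values = TRUE)$values)), numeric(1))
    expect_gte(min(mins), -1e-8)
  }
})

test_that("inverse spectrum inverts, with the 2x2 algebraic identity", {
  set.seed(7)
  X <- matrix(rnorm(2 * 5000), 2)
  X[2, ] <- X[2, ] + 0.5 * X[1, ]
  sp <- lag_window_spectrum(sample_covariance(X, 64), spectral_config(64, 256))
  g <- inverse_spectrum(sp)
  for (m in c(1, 100, 256)) {
    expect_lt(max(Mod(g$f[, , m] %*% sp$f[, , m] - diag(2))), 1e-8)
    # |g12|^2/(g11 g22) == |f12|^2/(f11 f22) for n = 2
    lhs <- Mod(g$f[1, 2, m])^2 / (Re(g$f[1, 1, m]) * Re(g$f[2, 2, m]))
    rhs <- Mod(sp$f[1, 2, m])^2 / (Re(sp$f[1, 1, m]) * Re(sp$f[2, 2, m]))
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  # diagonal input: reciprocal diagonal inverse
  nf <- 8
  fd <- array(0i, c(2, 2, nf))
  for (m in 1:nf) fd[, , m] <- diag(c(2, 5))
  gd <- inverse_spectrum(spectral_estimate(fd, seq(0, pi, length.out = nf)))
  expect_equal(Re(gd$f[1, 1, ]), rep(0.5, nf))
  expect_equal(Re(gd$f[2, 2, ]), rep(0.2, nf))
})

test_that("band averages are means over the correct half-open grids", {
  hz <- seq(0, 128, length.out = 1024)
  expect_equal(band_average(rep(3, 1024), "delta", hz), 3)
  for (b in names(frequency_bands())) {
    iv <- frequency_bands()[[b]]
    sel <- hz >= iv[1] & (if (b == "beta0") hz <= iv[2] else hz < iv[2])
    expect_equal(band_average(hz, b, hz), mean(hz[sel]))
  }
  expect_error(band_average(rep(1, 10), "delta", seq(20, 30, length.out = 10)),
               "no points")
})

test_that("Yule-Walker with AIC recovers a planted VAR(2)", {
  res <- vapply(1:20, function(s) {
    fit <- fit_ar(sim_var2(46080, s), max_order = 6)
    c(order = fit$order,
      err = if (fit$order >= 2)
        max(abs(fit$A[, , 1] - VAR2_A1), abs(fit$A[, , 2] - VAR2_A2))
      else Inf)
  }, numeric(2))
  expect_gte(mean(res["order", ] == 2), 0.9)
  expect_lte(max(res["err", ][res["order", ] == 2]), 0.05)
})

test_that("white noise yields near-zero AR coefficients; degenerate input errors", {
  set.seed(30)
  fit <- fit_ar(matrix(rnorm(2 * 46080), 2), max_order = 6)
  expect_lt(max(abs(fit$A)), 0.05)
  expect_error(fit_ar(matrix(rnorm(200), 2), max_order = 0), "max_order")
  # duplicated channel: singular Yule-Walker system
  x <- rnorm(1000)
  expect_error(fit_ar(rbind(x, x), max_order = 3), "singular|Yule")
})

test_that("scaling a channel scales its auto-spectrum; band averages are grid-stable", {
  set.seed(9)
  X <- matrix(rnorm(2 * 8192), 2)
  X[2, ] <- X[2, ] + 0.4 * X[1, ]
  cv1 <- sample_covariance(X, 128)
  X2 <- X; X2[1, ] <- 3 * X2[1, ]
  cv2 <- sample_covariance(X2, 128)
  sp1 <- lag_window_spectrum(cv1, spectral_config(128, 512))
  sp2 <- lag_window_spectrum(cv2, spectral_config(128, 512))
  expect_equal(Re(sp2$f[1, 1, ]), 9 * Re(sp1$f[1, 1, ]), tolerance = 1e-10)
  expect_equal(coherence(sp1, 1, 2, "alpha"), coherence(sp2, 1, 2, "alpha"),
               tolerance = 1e-10)
  # doubling the grid moves band averages by well under 1 %
  sp3 <- lag_window_spectrum(cv1, spectral_config(128, 1024))
  for (b in names(frequency_bands())) {
    b1 <- band_average(Re(sp1$f[1, 1, ]), b, sp1$hz)
    b3 <- band_average(Re(sp3$f[1, 1, ]), b, sp3$hz)
    expect_lt(abs(b3 - b1) / b1, 0.01)
  }
})
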