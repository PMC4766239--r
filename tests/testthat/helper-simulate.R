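# simulation helpers shared across tests

# Ricker spike train with the generator's cardiac geometry
spike_train <- function(n, times, rate = 256, sigma_s = 0.02) {
  t <- (-round(0.1 * rate):round(0.1 * rate)) / rate
  tmpl <- (1 - (t / sigma_s)^2) * exp(-t^2 / (2 * sigma_s^2))
  half <- (length(tmpl) - 1L) %/% 2L
  x <- numeric(n)
  for (t0 in times) {
    i <- (t0 - half):(t0 + half)
    k <- i >= 1 & i <= n
    x[i[k]] <- x[i[k]] + tmpl[k]
  }
  x
}

# raised-cosine blink train, 300 ms pulses
blink_train <- function(n, times, rate = 256, amp = 6) {
  p <- 0.5 * (1 - cos(2 * pi * seq_len(round(0.3 * rate)) / (round(0.3 * rate) + 1)))
  half <- length(p) %/% 2L
  x <- numeric(n)
  for (b in times) {
    i <- b:(b + length(p) - 1L) - half
    k <- i >= 1 & i <= n
    x[i[k]] <- x[i[k]] + amp * p[k]
  }
  x
}

# chain-coupled trivariate system x1 -> x2 -> x3 (lag-1 couplings 0.8)
sim_chain <- function(T, seed) {
  set.seed(seed)
  x1 <- rnorm(T + 2)
  x2 <- numeric(T + 2); x3 <- numeric(T + 2)
  for (t in 2:(T + 2)) {
    x2[t] <- 0.8 * x1[t - 1] + rnorm(1)
    x3[t] <- 0.8 * x2[t - 1] + rnorm(1)
  }
  out <- rbind(x1, x2, x3)[, 3:(T + 2)]
  rownames(out) <- c("x1", "x2", "x3")
  out
}

sim_independent <- function(T, seed, n = 3) {
  set.seed(seed)
  matrix(rnorm(n * T), n)
}

# stable bivariate VAR(2) with known coefficients
VAR2_A1 <- matrix(c(0.5, 0.1, 0.0, 0.3), 2, 2)
VAR2_A2 <- matrix(c(-0.2, 0.0, 0.1, -0.15), 2, 2)

sim_var2 <- function(T, seed, burn = 200) {
  set.seed(seed)
  x <- matrix(0, 2, T + burn)
  for (t in 3:(T + burn))
    x[, t] <- VAR2_A1 %*% x[, t - 1] + VAR2_A2 %*% x[, t - 2] + rnorm(2)
  x[, (burn + 1):(T + burn)]
}

# planted oblique two-factor population (loadings 0.7, factor correlation 0.3)
factor_population <- function() {
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  L <- matrix(0, 10, 2)
  L[1:5, 1] <- 0.7
  L[6:10, 2] <- 0.7
  Sig <- L %*% Phi %*% t(L)
  diag(Sig) <- 1
  list(L = L, Phi = Phi, chol = chol(Sig))
}

sim_factor_data <- function(n, seed, pop = factor_population()) {
  set.seed(seed)
  matrix(rnorm(n * 10), n) %*% pop$chol
}
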