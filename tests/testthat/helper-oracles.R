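# Shared fixtures and independent oracles, all generated in code.

# Random stable VAR with a general (cross-correlated) innovation covariance.
rand_stable_var <- function(d, p, seed, max_radius = 0.9) {
  set.seed(seed)
  repeat {
    A <- lapply(seq_len(p), function(k) matrix(rnorm(d * d, sd = 0.3), d, d))
    vm <- var_model(A, diag(d))
    rho <- spectral_radius(vm)
    if (rho < 1) {
      # shrink toward a comfortable stability margin
      sc <- if (rho > max_radius) max_radius / rho else 1
      A <- lapply(seq_along(A), function(k) A[[k]] * sc^k)
      break
    }
  }
  R <- matrix(rnorm(d * d, sd = 0.4), d, d)
  Sigma <- diag(d) + crossprod(R)   # SPD with cross terms
  var_model(A, Sigma, n_effective = 1000)
}

# Closed-form bivariate Geweke directed spectra for a VAR(1) with diagonal
# innovation covariance, evaluated with scalar arithmetic (an independent
# code path from the package's matrix pipeline).
bivar_geweke_oracle <- function(A1, sig1, sig2, omega) {
  f_m2i <- f_i2m <- numeric(length(omega))
  for (k in seq_along(omega)) {
    z <- exp(-1i * omega[k])
    a11 <- 1 - A1[1, 1] * z; a12 <- -A1[1, 2] * z
    a21 <- -A1[2, 1] * z;    a22 <- 1 - A1[2, 2] * z
    det <- a11 * a22 - a12 * a21
    h11 <- a22 / det; h12 <- -a12 / det
    h21 <- -a21 / det; h22 <- a11 / det
    S11 <- Mod(h11)^2 * sig1 + Mod(h12)^2 * sig2
    S22 <- Mod(h21)^2 * sig1 + Mod(h22)^2 * sig2
    f_m2i[k] <- log(S22 / (Mod(h22)^2 * sig2))
    f_i2m[k] <- log(S11 / (Mod(h11)^2 * sig1))
  }
  list(f_M_to_I = f_m2i, f_I_to_M = f_i2m)
}

# Simulate n samples from a var_model (ground-truth generator for
# recovery tests).
simulate_var <- function(vm, n, seed, burn = 200) {
  set.seed(seed)
  d <- vm$d; p <- vm$p
  ch <- chol(vm$Sigma)
  x <- matrix(0, n + burn, d)
  for (t in (p + 1):(n + burn)) {
    mu <- numeric(d)
    for (k in seq_len(p)) mu <- mu + vm$A[[k]] %*% x[t - k, ]
    x[t, ] <- mu + drop(rnorm(d) %*% ch)
  }
  x[(burn + 1):(burn + n), , drop = FALSE]
}

# Swap the Model and Imitator blocks of an epoch (role relabeling).
relabel_epoch <- function(ep) {
  N <- ep$N
  ep$data <- ep$data[, c(N + seq_len(N), seq_len(N)), drop = FALSE]
  ep
}

# Small white-noise dyad epoch.
white_epoch <- function(L = 204, N = 2, fs = 10.17, seed = 1) {
  set.seed(seed)
  dyad_epoch(matrix(rnorm(L * 2 * N), L, 2 * N), N, fs)
}
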