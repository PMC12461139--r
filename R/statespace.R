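#' Convert a fitted VAR to innovations-form state space
#'
#' Companion/innovations construction: with state
#' `S_t = [X_{t-1}; ...; X_{t-p}]` of dimension `m = d*p`,
#' `S_{t+1} = A S_t + K W_t` and `X_t = C S_t + W_t`, where `A` is the
#' companion matrix, `C = [A_1 ... A_p]`, `K = [I; 0; ...; 0]` and the
#' innovation covariance equals the VAR residual covariance. The implied
#' second-order statistics (autocovariances, spectra) are identical to the
#' VAR's.
#'
#' @param var a `var_model` from [fit_var()].
#' @return object of class `state_space_model` with fields `A` (`m x m`),
#'   `C` (`d x m`), `K` (`m x d`), `SigmaW`, `p`, `d`, `fs`.
#' @param fs sampling frequency carried along for frequency conversion.
#' @export
var_to_state_space <- function(var, fs = NA_real_) {
  stopifnot(inherits(var, "var_model"))
  rho <- spectral_radius(var)
  if (rho >= 1)
    stop(sprintf("unstable VAR (companion spectral radius %.4f >= 1)", rho))
  d <- var$d; p <- var$p; m <- d * p
  A <- companion_matrix(var)
  C <- do.call(cbind, var$A)
  K <- rbind(diag(d), matrix(0, m - d, d))
  structure(list(A = A, C = C, K = K, SigmaW = var$Sigma, p = p, d = d,
                 m = m, fs = fs, spectral_radius = rho),
            class = "state_space_model")
}

#' Uniform frequency grid from 0 to Nyquist
#'
#' @param fs sampling frequency (Hz).
#' @param n number of grid points (default 513).
#' @return object of class `frequency_grid` with fields `f` (Hz) and
#'   `omega` (normalized angular frequency `2*pi*f/fs` in `[0, pi]`).
#' @export
frequency_grid <- function(fs, n = 513L) {
  f <- seq(0, fs / 2, length.out = n)
  structure(list(f = f, omega = 2 * pi * f / fs, fs = fs, n = as.integer(n)),
            class = "frequency_grid")
}

#' Transfer function of a state-space model
#'
#' `H(omega) = I + C (I - A e^{-i omega})^{-1} K e^{-i omega}`, the filter
#' mapping the innovation spectrum to the observation spectrum.
#'
#' @param ssm a `state_space_model`.
#' @param grid a [frequency_grid()].
#' @return complex array `n_freq x d x d`.
#' @export
transfer_function <- function(ssm, grid) {
  stopifnot(inherits(ssm, "state_space_model"))
  Hc <- cpp_transfer(ssm$A, ssm$C, ssm$K, grid$omega)
  aperm(Hc, c(3, 1, 2))
}

#' Power spectral density matrix of a state-space model
#'
#' `S_X(omega) = H(omega) SigmaW H*(omega)`; Hermitian positive
#' semidefinite at every frequency. Spectra are one-sided over
#' `omega in [0, pi]`; the process covariance is recovered as
#' `(1/2pi) * integral of S_X over (-pi, pi]` (see [stationary_cov()]).
#'
#' @inheritParams transfer_function
#' @return complex array `n_freq x d x d`.
#' @export
psd_matrix <- function(ssm, grid) {
  H <- transfer_function(ssm, grid)
  d <- ssm$d
  S <- array(0i, dim = dim(H))
  for (k in seq_len(grid$n)) {
    Hk <- matrix(H[k, , ], d, d)
    Sk <- Hk %*% ssm$SigmaW %*% Conj(t(Hk))
    S[k, , ] <- (Sk + Conj(t(Sk))) / 2   # enforce exact Hermitianity
  }
  S
}

#' Model-implied stationary covariance (Lyapunov solution)
#'
#' Solves the discrete Lyapunov equation for the companion-state covariance
#' `P = A P A' + K SigmaW K'` by vectorization and returns the observation
#' covariance `Gamma_0 = C P C' + SigmaW`. Used as the closed-form oracle
#' for the spectral integral `(1/2pi) int S_X(omega) d omega`.
#'
#' @param ssm a `state_space_model`.
#' @return `d x d` covariance matrix.
#' @export
stationary_cov <- function(ssm) {
  stopifnot(inherits(ssm, "state_space_model"))
  m <- ssm$m
  Q <- ssm$K %*% ssm$SigmaW %*% t(ssm$K)
  vecP <- solve(diag(m * m) - kronecker(ssm$A, ssm$A), as.vector(Q))
  P <- matrix(vecP, m, m)
  G0 <- ssm$C %*% P %*% t(ssm$C) + ssm$SigmaW
  (G0 + t(G0)) / 2
}

#' Fit a stable state-space model to an epoch, with a stability gate
#'
#' Fits the VAR at the given (or MDL-selected) order; if the companion
#' spectral radius is `>= 1` the fit is retried with a small ridge penalty,
#' and if still unstable the epoch is rejected.
#'
#' @inheritParams fit_var
#' @param p order; `NULL` selects it by [select_order_mdl()].
#' @param p_max maximum order for MDL selection.
#' @param ridge ridge penalty used on refit after an unstable OLS fit.
#' @return a `state_space_model` with attribute `"order"` = order used and
#'   `"ridged"` = whether the ridge refit was needed.
#' @export
fit_epoch_ssm <- function(epoch, p = NULL, p_max = 2L, ridge = 1e-6) {
  fs <- if (inherits(epoch, "dyad_epoch")) epoch$fs else NA_real_
  if (is.null(p)) p <- select_order_mdl(epoch, p_max = p_max)
  fit <- fit_var(epoch, p)
  ridged <- FALSE
  if (spectral_radius(fit) >= 1) {
    fit <- fit_var(epoch, p, ridge = ridge)
    ridged <- TRUE
  }
  ssm <- var_to_state_space(fit, fs = fs)   # errors if still unstable
  attr(ssm, "order") <- p
  attr(ssm, "ridged") <- ridged
  ssm
}
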