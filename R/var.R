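#' Fit a vector autoregression by ordinary least squares
#'
#' `X_t = A_1 X_{t-1} + ... + A_p X_{t-p} + e_t`, no intercept (channels are
#' normalized first). The residual covariance uses denominator `L - p`
#' (the number of regression rows).
#'
#' @param epoch a [dyad_epoch()] or plain numeric matrix (time x channels).
#' @param p model order (integer >= 1).
#' @param ridge optional ridge penalty added to the regressor Gram matrix
#'   (scaled by the number of rows); 0 for plain OLS.
#' @return object of class `var_model` with fields `A` (list of `d x d`
#'   coefficient matrices), `Sigma`, `p`, `d`, `n_effective`.
#' @export
fit_var <- function(epoch, p, ridge = 0) {
  X <- if (inherits(epoch, "dyad_epoch")) epoch$data else as.matrix(epoch)
  L <- nrow(X); d <- ncol(X); p <- as.integer(p)
  if (p < 1L) stop("order p must be >= 1")
  if (L - p <= d * p)
    stop("too few samples: need L - p > d*p rows (L = ", L,
         ", d = ", d, ", p = ", p, ")")
  n <- L - p
  Y <- X[(p + 1L):L, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(k)
    X[(p + 1L - k):(L - k), , drop = FALSE]))
  if (ridge > 0) {
    G <- crossprod(Z) + diag(ridge * n, ncol(Z))
    B <- solve(G, crossprod(Z, Y))
  } else {
    # Band-limited signals sampled well above their bandwidth make lagged
    # regressors nearly collinear; only flag genuine rank deficiency.
    qz <- qr(Z, tol = 1e-12)
    if (qz$rank < ncol(Z))
      stop("rank-deficient regressor matrix (collinear channels); ",
           "consider refitting with a small ridge penalty")
    B <- qr.coef(qz, Y)
  }
  resid <- Y - Z %*% B
  Sigma <- crossprod(resid) / n
  A <- lapply(seq_len(p), function(k)
    t(B[((k - 1L) * d + 1L):(k * d), , drop = FALSE]))
  structure(list(A = A, Sigma = Sigma, p = p, d = d, n_effective = n),
            class = "var_model")
}

#' Construct a VAR model from known coefficients
#'
#' Builds the same object [fit_var()] estimates, from given coefficient
#' matrices and innovation covariance — e.g. to analyze a theoretical
#' model or to feed simulation ground truth through the spectral pipeline.
#'
#' @param A list of `d x d` coefficient matrices (lag 1 first), or a
#'   single matrix for a VAR(1).
#' @param Sigma innovation covariance (`d x d`, symmetric PSD).
#' @param n_effective nominal sample size (used only by order-selection
#'   formulas).
#' @return a `var_model`.
#' @export
var_model <- function(A, Sigma, n_effective = Inf) {
  if (is.matrix(A)) A <- list(A)
  d <- nrow(A[[1L]])
  stopifnot(all(vapply(A, function(a) all(dim(a) == d), logical(1))),
            all(dim(Sigma) == d),
            max(abs(Sigma - t(Sigma))) < 1e-12)
  structure(list(A = A, Sigma = Sigma, p = length(A), d = d,
                 n_effective = n_effective),
            class = "var_model")
}

#' Companion matrix and spectral radius of a VAR
#'
#' @param var a `var_model` (or list of coefficient matrices).
#' @return the `d*p x d*p` companion matrix.
#' @export
companion_matrix <- function(var) {
  A <- if (inherits(var, "var_model")) var$A else var
  p <- length(A); d <- nrow(A[[1L]])
  top <- do.call(cbind, A)
  if (p == 1L) return(top)
  rbind(top, cbind(diag(d * (p - 1L)), matrix(0, d * (p - 1L), d)))
}

#' @rdname companion_matrix
#' @return `spectral_radius`: the largest eigenvalue modulus (stability
#'   requires it to be `< 1`).
#' @export
spectral_radius <- function(var) {
  max(Mod(eigen(companion_matrix(var), only.values = TRUE)$values))
}

#' Select the VAR order by Minimum Description Length
#'
#' Evaluates `MDL(p) = log det Sigma_hat(p) + p * d^2 * log(n_eff) / n_eff`
#' for `p = 1 .. p_max` (with `n_eff = L - p`) and returns the minimizer;
#' ties go to the smaller order. The small default `p_max = 2` reflects the
#' short inter-participant delays expected at ~10 Hz sampling (one or two
#' samples, 100-200 ms) and the short epochs the model is fitted to.
#'
#' @inheritParams fit_var
#' @param p_max largest order considered (default 2).
#' @return the selected order (integer).
#' @export
select_order_mdl <- function(epoch, p_max = 2L, ridge = 0) {
  p_max <- as.integer(p_max)
  if (p_max < 1L) stop("p_max must be >= 1")
  if (p_max == 1L) return(1L)
  crit <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var(epoch, p, ridge = ridge)
    d <- fit$d; n <- fit$n_effective
    ld <- logdet_hermitian(ridge_floor(fit$Sigma))
    ld + p * d^2 * log(n) / n
  }, numeric(1))
  which.min(crit)
}

# Floor a covariance away from singularity before taking log-determinants:
# short epochs can yield numerically singular residual covariances, on which
# the log-determinant interdependence measures diverge.
ridge_floor <- function(Sigma, rel = 1e-8) {
  d <- nrow(Sigma)
  Sigma + diag(rel * sum(diag(Sigma)) / d, d)
}
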