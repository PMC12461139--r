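#' Phase-randomization surrogate of a multichannel series
#'
#' Per channel: Fourier transform, replacement of the phase of every
#' non-DC, non-Nyquist bin by an independent uniform draw on `[0, 2*pi)`,
#' conjugate symmetry enforcement, inverse transform. The amplitude
#' spectrum (hence the power spectrum and autocorrelation) of each channel
#' is preserved exactly while all phase structure — including cross-channel
#' phase relations, i.e. any lead/lag dependence between the participants —
#' is destroyed. Phases are drawn independently per channel and per bin: a
#' common phase vector would preserve cross-spectra and defeat the purpose
#' of the null.
#'
#' For even length the Nyquist-bin phase is fixed at 0 (the bin magnitude
#' is kept); the DC bin is untouched, so column means are preserved.
#'
#' @param x real matrix (time x channels) or vector, `L >= 4`.
#' @param seed integer seed; draws are made channel-by-channel in column
#'   order, so results are fully reproducible.
#' @return surrogate matrix of the same shape.
#' @export
phase_randomize <- function(x, seed) {
  if (is.complex(x)) stop("input must be real")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  L <- nrow(x)
  if (L < 4L) stop("need at least 4 samples")
  even <- L %% 2L == 0L
  n_free <- if (even) L / 2L - 1L else (L - 1L) / 2L   # bins 2..(L/2) 1-based
  out <- x
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  for (j in seq_len(ncol(x))) {
    X <- fft(x[, j])
    phases <- runif(n_free, 0, 2 * pi)
    amp <- Mod(X)
    Y <- X
    idx <- seq.int(2L, 1L + n_free)
    Y[idx] <- amp[idx] * exp(1i * phases)
    if (even) Y[L / 2L + 1L] <- amp[L / 2L + 1L]   # Nyquist phase 0
    Y[L + 2L - idx] <- Conj(Y[idx])
    out[, j] <- Re(fft(Y, inverse = TRUE)) / L
  }
  if (vec) drop(out) else out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Surrogate ensemble thresholds for the directed spectra
#'
#' Generates `n_surrogates` phase-randomized copies of the epoch and runs
#' each through the identical modeling path as the original data (same
#' order-selection policy, same stability gate, same grid), then averages
#' the directed spectra over the ensemble. The per-frequency ensemble means
#' are the significance thresholds: an observed directed value is
#' significant at a frequency only if it exceeds the surrogate mean there.
#'
#' @param epoch a [dyad_epoch()] (already preprocessed/normalized).
#' @param n_surrogates ensemble size (default 10).
#' @param seed master seed; per-surrogate seeds are derived
#'   deterministically.
#' @param grid a [frequency_grid()]; defaults to 513 points.
#' @param p_max maximum VAR order for MDL selection.
#' @param statistic `"mean"` (default) or `"percentile95"`.
#' @return object of class `surrogate_ensemble` with fields
#'   `mean_f_M_to_I`, `mean_f_I_to_M`, `n_surrogates`, `grid`,
#'   `decompositions` (list).
#' @export
surrogate_threshold <- function(epoch, n_surrogates = 10L, seed = 1L,
                                grid = NULL, p_max = 2L,
                                statistic = c("mean", "percentile95")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(epoch, "dyad_epoch"))
  if (n_surrogates < 1L) stop("need at least one surrogate")
  if (is.null(grid)) grid <- frequency_grid(epoch$fs)
  decs <- vector("list", n_surrogates)
  for (s in seq_len(n_surrogates)) {
    xs <- phase_randomize(epoch$data, seed = derive_seed(seed, s))
    se <- epoch; se$data <- xs
    dec <- tryCatch(
      mir_decompose(fit_epoch_ssm(se, p_max = p_max), grid),
      error = function(e) NULL)
    decs[[s]] <- dec
  }
  ok <- !vapply(decs, is.null, logical(1))
  if (!any(ok)) stop("all surrogate fits failed (unstable models)")
  decs <- decs[ok]
  m2i <- vapply(decs, function(d) d$f_M_to_I, numeric(grid$n))
  i2m <- vapply(decs, function(d) d$f_I_to_M, numeric(grid$n))
  m2i <- matrix(m2i, nrow = grid$n); i2m <- matrix(i2m, nrow = grid$n)
  agg <- switch(statistic,
    mean = rowMeans,
    percentile95 = function(m) apply(m, 1L, stats::quantile, probs = 0.95))
  structure(list(n_surrogates = length(decs), grid = grid,
                 mean_f_M_to_I = agg(m2i), mean_f_I_to_M = agg(i2m),
                 statistic = statistic, decompositions = decs),
            class = "surrogate_ensemble")
}

#' Apply surrogate significance masks to a decomposition
#'
#' Produces the causal spectrum of `dec` with per-frequency boolean masks:
#' a directed value is flagged significant where it exceeds the surrogate
#' ensemble threshold at that frequency.
#'
#' @param dec a `spectral_decomposition` of the observed epoch.
#' @param ens a `surrogate_ensemble` on the same grid.
#' @return a `causal_spectrum` with `mask_M_to_I` and `mask_I_to_M` set.
#' @export
apply_significance <- function(dec, ens) {
  stopifnot(inherits(dec, "spectral_decomposition"),
            inherits(ens, "surrogate_ensemble"))
  if (dec$grid$n != ens$grid$n ||
      max(abs(dec$grid$f - ens$grid$f)) > 1e-12)
    stop("frequency grids of decomposition and ensemble differ")
  cs <- causal_spectrum(dec)
  cs$mask_M_to_I <- dec$f_M_to_I > ens$mean_f_M_to_I
  cs$mask_I_to_M <- dec$f_I_to_M > ens$mean_f_I_to_M
  cs
}
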