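#' Butterworth band-pass filter applied identically to every channel
#'
#' Designs a digital Butterworth band-pass (analog prototype mapped by the
#' bilinear transform, band edges are the -3 dB points) and applies it to
#' each column. The default is forward-backward application
#' (`mode = "zero_phase"`), which cancels the filter's phase and squares its
#' magnitude response; `mode = "forward"` applies a single causal pass.
#' Either way every channel of both participants receives identical
#' coefficients, so any filter-induced delay is common to all channels and
#' cannot create spurious lead/lag structure between participants.
#'
#' @param x numeric matrix (time x channels) or vector.
#' @param fs sampling frequency, Hz.
#' @param low,high band edges in Hz (defaults 0.008 and 0.2, the
#'   conventional fNIRS hemodynamic band).
#' @param order Butterworth order of the analog prototype (default 5).
#' @param mode `"zero_phase"` (forward-backward) or `"forward"`.
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs, low = 0.008, high = 0.2, order = 5L,
                            mode = c("zero_phase", "forward")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (nrow(x) <= 3L * order)
    stop("time series too short for a filter of order ", order)
  sos <- butter_bandpass_sos(low, high, fs, order)
  run <- function(col) {
    for (k in seq_len(nrow(sos))) {
      col <- as.numeric(signal::filter(signal::Arma(b = sos[k, 1:3],
                                                    a = sos[k, 4:6]), col))
    }
    col
  }
  out <- apply(x, 2L, function(col) {
    if (mode == "zero_phase") rev(run(rev(run(col)))) else run(col)
  })
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec) drop(out) else out
}

# Butterworth band-pass as second-order sections.  A single transfer
# function of order 2n has its roots clustered near z = 1 for narrow
# normalized bands (hemodynamic bands at ~10 Hz sampling), which makes the
# expanded polynomial coefficients numerically useless; the biquad cascade
# evaluates the same filter stably.  Closed-form design: analog prototype
# poles -> lowpass-to-bandpass transform -> bilinear map.
butter_bandpass_sos <- function(low, high, fs, order) {
  wl <- tan(pi * low / fs); wh <- tan(pi * high / fs)
  B <- wh - wl; W02 <- wl * wh
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  # each prototype pole maps to a quadratic in s: s^2 - p*B*s + W0^2 = 0
  s_poles <- c(vapply(proto, function(p) {
    disc <- sqrt((p * B)^2 - 4 * W02)
    (p * B + disc) / 2
  }, complex(1)), vapply(proto, function(p) {
    disc <- sqrt((p * B)^2 - 4 * W02)
    (p * B - disc) / 2
  }, complex(1)))
  z_poles <- (1 + s_poles) / (1 - s_poles)               # bilinear, T = 2
  # group into second-order sections: complex poles with their conjugates,
  # real poles (from the real prototype pole of odd orders) paired together
  tol <- 1e-12
  cplx <- z_poles[Im(z_poles) > tol]
  re_p <- sort(Re(z_poles[abs(Im(z_poles)) <= tol]))
  quads <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(re_p)) {
    stopifnot(length(re_p) %% 2 == 0)
    for (i in seq(1, length(re_p), by = 2)) {
      p1 <- re_p[i]; p2 <- re_p[i + 1]
      quads[[length(quads) + 1]] <- c(1, -(p1 + p2), p1 * p2)
    }
  }
  wc <- 2 * atan(sqrt(W02))                              # center frequency
  zc <- exp(1i * wc)
  sos <- t(vapply(quads, function(a) {
    b <- c(1, 0, -1)                                     # zeros at +1, -1
    g <- abs(sum(a * zc^(0:-2)) / sum(b * zc^(0:-2)))    # unit gain at wc
    c(b * g, a)
  }, numeric(6)))
  sos
}

#' Magnitude response of the band-pass filter at given frequencies
#'
#' Closed-form digital Butterworth band-pass magnitude via the bilinear
#' frequency mapping `Omega = tan(pi f / fs)`; the zero-phase mode squares
#' the single-pass magnitude.
#'
#' @inheritParams bandpass_filter
#' @param f frequencies (Hz) at which to evaluate.
#' @return numeric vector of linear-magnitude gains.
#' @export
bandpass_gain <- function(f, fs, low = 0.008, high = 0.2, order = 5L,
                          mode = c("zero_phase", "forward")) {
  mode <- match.arg(mode)
  wl <- tan(pi * low / fs); wh <- tan(pi * high / fs)
  w <- tan(pi * f / fs)
  g2 <- 1 / (1 + ((w^2 - wl * wh) / (w * (wh - wl)))^(2 * order))
  g <- sqrt(g2)
  if (mode == "zero_phase") g^2 else g
}

#' Z-normalize every channel of an epoch
#'
#' Subtracts the column mean and divides by the column standard deviation
#' (denominator `n - 1`), so each channel has mean 0 and unit sample
#' variance. Idempotent up to floating-point error. Applied per epoch: the
#' epoch is the modeling unit, and normalization puts all channels on the
#' innovation scale the state-space fit assumes.
#'
#' @param epoch a [dyad_epoch()] (or plain numeric matrix).
#' @return the same type of object, normalized.
#' @export
znormalize <- function(epoch) {
  mat <- if (inherits(epoch, "dyad_epoch")) epoch$data else as.matrix(epoch)
  sds <- apply(mat, 2L, sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    nm <- colnames(mat)[zero] %||% as.character(zero)
    stop("zero-variance channel(s): ", paste(nm, collapse = ", "))
  }
  out <- sweep(sweep(mat, 2L, colMeans(mat)), 2L, sds, "/")
  if (inherits(epoch, "dyad_epoch")) {
    epoch$data <- out
    epoch
  } else out
}
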