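#' Short-distance-channel causal baseline for a dyad
#'
#' Runs the identical modeling path (order selection, state-space fit,
#' spectral decomposition, band integration) on the short-distance channel
#' (SDC) blocks of Model and Imitator for each of the dyad's trials and
#' returns the mean signed band value. SDCs carry scalp and systemic
#' physiology but no cortical task signal, so this mean estimates the
#' spurious causal intensity that shared confounders (e.g. Mayer waves)
#' induce, and calibrates the direction decision.
#'
#' @param sdc_epochs list of [dyad_epoch()] objects of the SDC channels,
#'   one per trial.
#' @param band_hz integration band (Hz).
#' @param grid optional [frequency_grid()].
#' @param p_max maximum VAR order.
#' @param normalize z-normalize each epoch first (default `TRUE`).
#' @param use_mask apply surrogate significance masking, exactly as in the
#'   main analysis path (default `TRUE`; the baseline must be computed by
#'   the identical method, or its scale is incommensurate with the epoch
#'   values it calibrates).
#' @param n_surrogates,seed surrogate ensemble settings when masking.
#' @param pairing `"pairwise"` (default) analyzes each Model-SDC /
#'   Imitator-SDC channel pair as a bivariate dyad and averages the signed
#'   values over pairs and trials; `"block"` analyzes the full SDC blocks
#'   as one multivariate epoch. The log-determinant causal measures scale
#'   with block dimension, so the pairwise variant keeps the baseline
#'   commensurate with low-dimensional region statistics and averages
#'   away more estimation noise.
#' @return the mean signed band value (`C_short`), with attribute
#'   `"per_trial"` holding the per-trial values.
#' @export
short_channel_baseline <- function(sdc_epochs, band_hz = c(0.008, 0.08),
                                   grid = NULL, p_max = 2L,
                                   normalize = TRUE, use_mask = TRUE,
                                   n_surrogates = 10L, seed = 1L,
                                   pairing = c("pairwise", "block"),
                                   mask_convention = "frequency") {
  pairing <- match.arg(pairing)
  if (!length(sdc_epochs))
    stop("no SDC epochs supplied; a zero baseline must be requested ",
         "explicitly, not silently assumed")
  one_value <- function(ep, sub_seed) {
    g <- grid %||% frequency_grid(ep$fs)
    if (normalize) ep <- znormalize(ep)
    tryCatch({
      dec <- mir_decompose(fit_epoch_ssm(ep, p_max = p_max), g)
      if (use_mask) {
        ens <- surrogate_threshold(ep, n_surrogates = n_surrogates,
                                   seed = sub_seed, grid = g, p_max = p_max)
        cs <- apply_significance(dec, ens)
      } else {
        cs <- causal_spectrum(dec)
      }
      band_integrate(cs, band_hz, use_mask = use_mask,
                     mask_convention = mask_convention)$value
    }, error = function(e) NA_real_)   # unstable fit: excluded from mean
  }
  vals <- vapply(seq_along(sdc_epochs), function(i) {
    ep <- sdc_epochs[[i]]
    if (pairing == "block" || ep$N == 1L)
      return(one_value(ep, derive_seed(seed, i)))
    pv <- vapply(seq_len(ep$N), function(j) {
      pe <- dyad_epoch(ep$data[, c(j, ep$N + j), drop = FALSE], 1L, ep$fs,
                       condition = ep$condition, region = ep$region,
                       dyad_id = ep$dyad_id, trial_index = ep$trial_index)
      one_value(pe, derive_seed(seed, i, j))
    }, numeric(1))
    if (all(is.na(pv))) NA_real_ else mean(pv, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(vals)))
    stop("no SDC trial yielded a stable model; baseline undefined")
  if (anyNA(vals))
    warning(sum(is.na(vals)), " SDC trial(s) excluded (unstable model)")
  structure(mean(vals, na.rm = TRUE), per_trial = vals)
}

#' Direction decision for one epoch
#'
#' Applies the calibrated rule: the influence is Model-to-Imitator if the
#' epoch's signed band value exceeds `c_short + epsilon`,
#' Imitator-to-Model if it falls below `c_short - epsilon`, and absent
#' otherwise; `epsilon` defines the no-causality band around the SDC
#' baseline. Note the rule is relative to the baseline, not to zero: a
#' positive `c_value` below `c_short - epsilon` is still classified
#' Imitator-to-Model.
#'
#' @param c_value signed band-integrated causal value of the epoch.
#' @param c_short SDC baseline of the dyad (see
#'   [short_channel_baseline()]).
#' @param epsilon half-width of the no-causality band (default `1e-4`).
#' @return object of class `causal_decision` with fields `direction`
#'   (`"M_to_I"`, `"I_to_M"` or `"none"`), `intensity` (`abs(c_value)`),
#'   `c_value`, `c_short`, `epsilon`.
#' @export
decide_direction <- function(c_value, c_short, epsilon = 1e-4) {
  if (epsilon <= 0) stop("epsilon must be positive")
  direction <-
    if (c_value > c_short + epsilon) "M_to_I"
    else if (c_value < c_short - epsilon) "I_to_M"
    else "none"
  structure(list(direction = direction, intensity = abs(c_value),
                 c_value = c_value, c_short = c_short, epsilon = epsilon),
            class = "causal_decision")
}

#' Detection accuracy against ground truth
#'
#' For task intervals (ground truth direction Model-to-Imitator), accuracy
#' is the fraction of epochs decided `"M_to_I"`. For baseline intervals
#' (no true coupling), accuracy is the fraction decided `"none"`.
#'
#' @param decisions list of `causal_decision` objects, or a character
#'   vector of directions.
#' @param truth character vector of true directions (`"M_to_I"` or
#'   `"none"`), same length.
#' @param condition `"task"` or `"baseline"`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(decisions, truth, condition = c("task", "baseline")) {
  condition <- match.arg(condition)
  dirs <- if (is.character(decisions)) decisions
          else vapply(decisions, `[[`, character(1), "direction")
  if (!length(dirs)) stop("no decisions supplied")
  if (length(dirs) != length(truth))
    stop("decisions and truth have different lengths")
  target <- if (condition == "task") "M_to_I" else "none"
  mean(dirs == target)
}
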