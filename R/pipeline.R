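#' Default pipeline configuration
#'
#' Returns the full set of analysis settings with their defaults; any
#' element can be overridden via `...` (nested lists are merged).
#'
#' @param ... named overrides, e.g. `surrogate = list(n = 5)`.
#' @return nested list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = list(low_hz = 0.008, high_hz = 0.2, order = 5L,
                  mode = "zero_phase"),
    epoch = list(length = 204L, pre_onset = 10L),
    model = list(p_max = 2L, ridge = 1e-6),
    spectrum = list(n_freq = 513L),
    band = list(low_hz = 0.008, high_hz = 0.08, use_mask = TRUE,
                mask_convention = "frequency"),
    surrogate = list(n = 10L, statistic = "mean"),
    decision = list(epsilon = 1e-4, zero_baseline = FALSE),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the full causal analysis on one dyad recording
#'
#' Orchestrates the per-epoch chain: band-pass filter the whole recording;
#' extract fixed-length epochs per region and event; z-normalize; select
#' the model order (MDL, small maximum); fit the VAR / state-space model
#' with the stability gate; decompose the spectral interdependence into
#' directed and instantaneous terms; build phase-randomization surrogate
#' thresholds and mask insignificant frequencies; band-integrate the
#' masked directed difference; and decide the direction against the
#' dyad's short-distance-channel baseline. Epochs whose model fit fails
#' are reported and skipped; the pipeline continues.
#'
#' @param recording a [dyad_recording()].
#' @param events an [event_table()].
#' @param config a [pipeline_config()].
#' @param regions regions to analyze; default all non-SDC regions.
#' @param dyad_id label carried into the results.
#' @return list with `summary` (one row per epoch: dyad_id, region,
#'   condition, trial_index, order, c_value, intensity, c_short,
#'   direction), `spectra` (long per-frequency table), and `c_short`
#'   (named per-condition SDC baselines).
#' @export
run_analysis <- function(recording, events, config = pipeline_config(),
                         regions = NULL, dyad_id = "dyad01") {
  stopifnot(inherits(recording, "dyad_recording"),
            inherits(events, "event_table"))
  fs <- recording$fs
  all_regions <- unique(recording$region_map)
  if (is.null(regions)) regions <- setdiff(all_regions, "SDC")
  if (!length(regions)) stop("no regions to analyze")

  # Filtering removes out-of-band physiological artifacts from real
  # recordings.  Mode "off" skips it: band-pass filtering ahead of a VAR
  # fit drives the model's poles toward the unit circle and inflates
  # spurious causality (the classic filtering-and-Granger-causality
  # caveat); band-specific inference is better obtained by integrating the
  # causal spectrum over the band, which the pipeline does regardless.
  filt <- config$filter
  if (!identical(filt$mode, "off")) {
    recording$samples <- bandpass_filter(recording$samples, fs,
                                         low = filt$low_hz,
                                         high = filt$high_hz,
                                         order = filt$order, mode = filt$mode)
  }
  grid <- frequency_grid(fs, config$spectrum$n_freq)
  band <- c(config$band$low_hz, config$band$high_hz)
  task_conditions <- setdiff(unique(events$condition), "baseline")

  # SDC baseline per task condition, plus pooled value for baseline epochs
  c_short <- sdc_baselines(recording, events, task_conditions, grid, band,
                           config)

  summary_rows <- list(); spectra_rows <- list()
  for (ri in seq_along(regions)) {
    region <- regions[ri]
    eps <- extract_epochs(recording, events, region,
                          epoch_length = config$epoch$length,
                          pre_onset = config$epoch$pre_onset)
    for (ei in seq_along(eps)) {
      ep <- eps[[ei]]
      res <- tryCatch(
        analyze_epoch(ep, grid, band, config,
                      seed = derive_seed(config$seed, ri, ei)),
        error = function(e) {
          warning(sprintf("dyad %s, region %s, %s trial %d: %s",
                          dyad_id, region, ep$condition, ep$trial_index,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      cs_ref <- if (ep$condition %in% task_conditions)
        c_short[[ep$condition]] else c_short[["pooled"]]
      dec <- decide_direction(res$c_value, cs_ref,
                              epsilon = config$decision$epsilon)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        dyad_id = dyad_id, region = region, condition = ep$condition,
        trial_index = ep$trial_index, order = res$order,
        c_value = res$c_value, intensity = abs(res$c_value),
        c_short = cs_ref, direction = dec$direction,
        stringsAsFactors = FALSE)
      spectra_rows[[length(spectra_rows) + 1L]] <- data.frame(
        dyad_id = dyad_id, region = region, condition = ep$condition,
        trial_index = ep$trial_index, f = grid$f,
        f_M_to_I = res$dec$f_M_to_I, f_I_to_M = res$dec$f_I_to_M,
        C = res$cs$C, stringsAsFactors = FALSE)
    }
  }
  if (!length(summary_rows)) stop("no epoch was successfully analyzed")
  list(summary = do.call(rbind, summary_rows),
       spectra = do.call(rbind, spectra_rows),
       c_short = c_short)
}

analyze_epoch <- function(ep, grid, band, config, seed) {
  ep <- znormalize(ep)
  ssm <- fit_epoch_ssm(ep, p_max = config$model$p_max,
                       ridge = config$model$ridge)
  dec <- mir_decompose(ssm, grid)
  if (config$band$use_mask) {
    ens <- surrogate_threshold(ep, n_surrogates = config$surrogate$n,
                               seed = seed, grid = grid,
                               p_max = config$model$p_max,
                               statistic = config$surrogate$statistic)
    cs <- apply_significance(dec, ens)
  } else {
    cs <- causal_spectrum(dec)
  }
  bi <- band_integrate(cs, band, use_mask = config$band$use_mask,
                       mask_convention = config$band$mask_convention)
  list(c_value = bi$value, order = attr(ssm, "order"), dec = dec, cs = cs)
}

sdc_baselines <- function(recording, events, task_conditions, grid, band,
                          config) {
  has_sdc <- any(recording$region_map == "SDC")
  if (!has_sdc) {
    if (!isTRUE(config$decision$zero_baseline))
      stop("no SDC channels in the recording; set decision$zero_baseline ",
           "= TRUE to use an explicit zero baseline")
    out <- as.list(setNames(rep(0, length(task_conditions)), task_conditions))
    out$pooled <- 0
    return(out)
  }
  out <- list(); all_vals <- numeric(0)
  for (ci in seq_along(task_conditions)) {
    cond <- task_conditions[ci]
    eps <- extract_epochs(recording, events, "SDC",
                          epoch_length = config$epoch$length,
                          pre_onset = config$epoch$pre_onset,
                          conditions = cond)
    cs <- short_channel_baseline(eps, band_hz = band, grid = grid,
                                 p_max = config$model$p_max,
                                 use_mask = config$band$use_mask,
                                 n_surrogates = config$surrogate$n,
                                 seed = derive_seed(config$seed, 9000L, ci),
                                 mask_convention = config$band$mask_convention)
    out[[cond]] <- as.numeric(cs)
    all_vals <- c(all_vals, attr(cs, "per_trial"))
  }
  out$pooled <- mean(all_vals, na.rm = TRUE)
  out
}

#' Summarize analysis results, optionally scored against ground truth
#'
#' Produces per-region, per-condition accuracy (when truth is given) and
#' the region-mean directed spectra over task epochs — the group-level
#' summary showing whether the Model-to-Imitator spectrum dominates.
#'
#' @param results output of [run_analysis()], or a row-bound `summary`
#'   data.frame from several dyads (with matching `spectra`).
#' @param truth optional ground-truth data.frame with columns `condition`,
#'   `trial_index`, `true_direction` (and `dyad_id` if multi-dyad).
#' @return list with `accuracy` (data.frame or `NULL`), `intensity`
#'   (per region x condition mean intensity), `mean_spectra`.
#' @export
report <- function(results, truth = NULL) {
  summ <- if (is.data.frame(results)) results else results$summary
  if (is.null(summ) || !nrow(summ)) stop("no results to report")
  acc <- NULL
  if (!is.null(truth)) {
    keys <- intersect(c("dyad_id", "condition", "trial_index"),
                      intersect(names(summ), names(truth)))
    merged <- merge(summ, truth[, c(keys, "true_direction")], by = keys)
    if (nrow(merged) != nrow(summ))
      stop("ground truth does not cover all results (",
           nrow(merged), " of ", nrow(summ), " rows matched)")
    acc <- do.call(rbind, lapply(
      split(merged, list(merged$region, merged$condition), drop = TRUE),
      function(g) data.frame(
        region = g$region[1], condition = g$condition[1],
        n = nrow(g),
        accuracy = mean(ifelse(g$true_direction == "M_to_I",
                               g$direction == "M_to_I",
                               g$direction == "none")),
        stringsAsFactors = FALSE)))
    rownames(acc) <- NULL
  }
  intensity <- stats::aggregate(intensity ~ region + condition, data = summ,
                                FUN = mean)
  mean_spectra <- NULL
  if (!is.data.frame(results) && !is.null(results$spectra)) {
    sp <- results$spectra
    mean_spectra <- stats::aggregate(
      cbind(f_M_to_I, f_I_to_M, C) ~ region + condition + f,
      data = sp, FUN = mean)
  }
  list(accuracy = acc, intensity = intensity, mean_spectra = mean_spectra)
}
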