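#' Canonical hemodynamic response function
#'
#' Difference-of-gamma impulse response, normalized to unit peak, zero at
#' `t = 0` and for negative times. The main lobe peaks at `peak_delay`
#' seconds; a smaller, later gamma produces the post-stimulus undershoot.
#' Used by the simulator to turn the task "neural drive" into an HbO-like
#' response; real HbO responses differ in detail, but the smooth
#' band-limited shape and ~6 s peak latency are what matter for the
#' analysis band.
#'
#' @param t time in seconds (vectorized).
#' @param peak_delay peak latency of the main lobe, seconds (default 6).
#' @param undershoot_ratio amplitude ratio of the undershoot lobe
#'   (default 1/6).
#' @return numeric vector, unit peak amplitude.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_ratio = 1 / 6) {
  a1 <- 6
  b1 <- (a1 - 1) / peak_delay            # gamma mode (a-1)/b = peak_delay
  a2 <- 16
  b2 <- (a2 - 1) / (peak_delay * 16 / 6) # undershoot peaks ~16 s for 6 s main
  g <- function(x, a, b) ifelse(x > 0, stats::dgamma(x, shape = a, rate = b), 0)
  h <- g(t, a1, b1) - undershoot_ratio * g(t, a2, b2)
  peak <- stats::optimize(function(x) g(x, a1, b1) -
                            undershoot_ratio * g(x, a2, b2),
                          c(0, 3 * peak_delay), maximum = TRUE,
                          tol = 1e-10)$objective
  h / peak
}

#' Simulation configuration for a synthetic dyad
#'
#' Defaults emulate the dyadic imitation protocol: ~10.17 Hz sampling, ten
#' 20 s task trials per condition (hand and foot) in pseudo-random order,
#' each preceded by a 60 s rest, a shared ~0.1 Hz Mayer-wave confounder
#' with identical phase in both participants and in the short-distance
#' channels, an Imitator response that is the Model's task drive delayed by
#' one or two samples (100-200 ms), and AR(1) hemodynamic background plus
#' broadband measurement noise.
#'
#' @param fs sampling frequency, Hz.
#' @param n_trials trials per condition.
#' @param task_duration,baseline_duration seconds.
#' @param coupling_gain amplitude of the Imitator's (delayed) task
#'   response relative to the Model's; 0 removes the coupling.
#' @param coupling_lag Model-to-Imitator delay in samples (>= 1).
#' @param foot_extra_lag extra samples of delay for the foot condition
#'   (the foot response follows with a longer latency than the hand).
#' @param imitator_onset_delay additional Imitator onset delay, seconds.
#' @param confounder_amplitude,confounder_freq shared sinusoidal systemic
#'   confounder (Mayer waves, ~0.1 Hz).
#' @param noise_sd per-sample measurement noise standard deviation.
#' @param background_sd,background_ar AR(1) hemodynamic background level
#'   and coefficient.
#' @param hrf_peak_delay seconds, see [canonical_hrf()].
#' @param response_amplitude peak task-response amplitude (Model).
#' @param n_channels_region channels per participant in the simulated
#'   cortical region.
#' @param region_name name given to the simulated region.
#' @param n_sdc short-distance channels per participant.
#' @param seed integer seed; the full recording is reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(fs = 10.17, n_trials = 10L, task_duration = 20,
                       baseline_duration = 60, coupling_gain = 1.0,
                       coupling_lag = 2L, foot_extra_lag = 1L,
                       imitator_onset_delay = 0, confounder_amplitude = 0.05,
                       confounder_freq = 0.1, noise_sd = 0.5,
                       background_sd = 0.02, background_ar = 0.9,
                       hrf_peak_delay = 6, response_amplitude = 3,
                       n_channels_region = 1L, region_name = "M1",
                       n_sdc = 3L, seed = 1L) {
  cfg <- as.list(environment())
  if (task_duration <= 0 || baseline_duration <= 0)
    stop("durations must be positive")
  if (coupling_lag < 1L) stop("coupling_lag must be >= 1 sample")
  if (fs <= 2 * confounder_freq)
    stop("fs must exceed twice the confounder frequency")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate one dyad recording with known ground truth
#'
#' Builds a full-session recording: for each trial, a rest interval
#' followed by a task video interval. Model region channels carry an
#' HRF-convolved task boxcar plus AR(1) background, the shared-phase
#' confounder, and white noise; Imitator region channels carry the same
#' drive delayed by the condition's lag and scaled by `coupling_gain`
#' (coupling acts on the pre-HRF neural drive; both sides are then
#' HRF-convolved), plus their own independent background and noise and the
#' same-phase confounder; SDC channels carry only confounder plus noise.
#' Baseline events are placed end-aligned inside each rest interval
#' (ending 1 s before the video), so a standard epoch window fits without
#' touching the preceding task.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `recording` ([dyad_recording()]), `events`
#'   ([event_table()], conditions hand/foot/baseline), and `truth`
#'   (data.frame: condition, trial_index, true_direction, lag_samples).
#' @export
simulate_dyad <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(cfg$seed %% 2147483647))

  fs <- cfg$fs
  trial_len <- cfg$baseline_duration + cfg$task_duration
  n_total <- 2L * cfg$n_trials
  dur_total <- n_total * trial_len + 10          # 10 s tail pad
  L <- ceiling(dur_total * fs)
  t <- (seq_len(L) - 1) / fs

  conditions <- sample(rep(c("hand", "foot"), cfg$n_trials))
  onsets <- (seq_len(n_total) - 1) * trial_len + cfg$baseline_duration

  lag_of <- function(cond) {
    cfg$coupling_lag + round(cfg$imitator_onset_delay * fs) +
      if (cond == "foot") cfg$foot_extra_lag else 0L
  }

  # Pre-HRF neural drives: Model = task boxcar; Imitator = delayed, scaled
  drive_M <- numeric(L); drive_I <- numeric(L)
  for (k in seq_len(n_total)) {
    on_s <- round(onsets[k] * fs); off_s <- round((onsets[k] + cfg$task_duration) * fs)
    idx <- (on_s + 1L):min(off_s, L)
    drive_M[idx] <- 1
    d <- lag_of(conditions[k])
    idx_i <- pmin(idx + d, L)
    drive_I[idx_i] <- cfg$coupling_gain
  }
  hrf <- canonical_hrf(seq(0, 32, by = 1 / fs), cfg$hrf_peak_delay)
  conv_causal <- function(x, k) {
    out <- convolve(x, rev(k), type = "open")[seq_along(x)]
    out / fs                                      # discrete conv * dt
  }
  resp_M <- cfg$response_amplitude * conv_causal(drive_M, hrf)
  resp_I <- cfg$response_amplitude * conv_causal(drive_I, hrf)

  phi <- runif(1, 0, 2 * pi)                      # shared confounder phase
  conf <- cfg$confounder_amplitude * sin(2 * pi * cfg$confounder_freq * t + phi)

  ar1 <- function() {
    e <- rnorm(L)
    x <- as.numeric(stats::filter(e, cfg$background_ar, method = "recursive"))
    x / sd(x) * cfg$background_sd
  }
  make_channel <- function(resp) {
    gain <- runif(1, 0.8, 1.2)
    gain * resp + ar1() + conf + cfg$noise_sd * rnorm(L)
  }

  nR <- cfg$n_channels_region; nS <- cfg$n_sdc
  labels <- c(paste0("M_", cfg$region_name, "_", seq_len(nR)),
              paste0("I_", cfg$region_name, "_", seq_len(nR)),
              paste0("M_SDC_", seq_len(nS)),
              paste0("I_SDC_", seq_len(nS)))
  samples <- matrix(0, L, length(labels), dimnames = list(NULL, labels))
  for (j in seq_len(nR)) samples[, j] <- make_channel(resp_M)
  for (j in seq_len(nR)) samples[, nR + j] <- make_channel(resp_I)
  for (j in seq_len(2L * nS))
    samples[, 2L * nR + j] <- conf + cfg$noise_sd * rnorm(L)

  role_map <- setNames(c(rep("Model", nR), rep("Imitator", nR),
                         rep("Model", nS), rep("Imitator", nS)), labels)
  region_map <- setNames(c(rep(cfg$region_name, 2L * nR), rep("SDC", 2L * nS)),
                         labels)
  rec <- dyad_recording(samples, fs, labels, role_map, region_map)

  # Events: task trials plus end-aligned baseline windows inside each rest
  base_onsets <- onsets - cfg$task_duration - 1
  ev <- data.frame(onset = c(onsets, base_onsets),
                   duration = cfg$task_duration,
                   condition = c(conditions, rep("baseline", n_total)),
                   trial_index = c(seq_len(n_total), seq_len(n_total)))
  ev <- ev[order(ev$onset), ]
  events <- event_table(ev$onset, ev$duration, ev$condition, ev$trial_index)

  coupled <- cfg$coupling_gain > 0
  truth <- data.frame(
    condition = c(conditions, rep("baseline", n_total)),
    trial_index = c(seq_len(n_total), seq_len(n_total)),
    true_direction = c(rep(if (coupled) "M_to_I" else "none", n_total),
                       rep("none", n_total)),
    lag_samples = c(if (coupled) vapply(conditions, lag_of, numeric(1))
                    else rep(0, n_total), rep(0, n_total)),
    stringsAsFactors = FALSE)

  list(recording = rec, events = events, truth = truth, config = cfg)
}

#' Simulate a cohort of independent dyads
#'
#' @param n_dyads number of dyads.
#' @param cfg a [sim_config()] shared by all dyads (each gets a derived
#'   seed).
#' @param seed master seed.
#' @return list of `simulate_dyad()` results; each element gains a
#'   `dyad_id`.
#' @export
make_dataset <- function(n_dyads, cfg = sim_config(), seed = 1L) {
  stopifnot(n_dyads >= 1L)
  lapply(seq_len(n_dyads), function(i) {
    ci <- cfg
    ci$seed <- derive_seed(seed, i)
    out <- simulate_dyad(ci)
    out$dyad_id <- sprintf("dyad%02d", i)
    out$truth$dyad_id <- out$dyad_id
    out
  })
}

#' Write a simulated dataset to the package's CSV dialect
#'
#' One subdirectory per dyad containing `recording.csv`, `recording.yaml`
#' (channel map), `events.csv`, and `truth.csv`.
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the dyad directories.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(dataset, function(dy) {
    dd <- file.path(dir, dy$dyad_id)
    dir.create(dd, showWarnings = FALSE)
    write_recording(dy$recording, file.path(dd, "recording.csv"))
    write_events(dy$events, file.path(dd, "events.csv"))
    data.table::fwrite(dy$truth, file.path(dd, "truth.csv"))
    dd
  }, character(1))
  invisible(paths)
}
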