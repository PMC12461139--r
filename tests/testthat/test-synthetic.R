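test_that("canonical HRF peaks at the requested delay and starts at zero", {
  t <- seq(0, 40, by = 0.01)
  h <- canonical_hrf(t, peak_delay = 6)
  expect_equal(h[1], 0)
  expect_equal(t[which.max(h)], 6, tolerance = 0.05)
  expect_equal(max(h), 1, tolerance = 1e-5)
  expect_equal(canonical_hrf(-1), 0)
  # integral over a minute: positive and finite (quadrature)
  integ <- integrate(canonical_hrf, 0, 60)$value
  expect_true(is.finite(integ) && integ > 0)
})

test_that("simulated dyads honor the experimental design counts", {
  cfg <- sim_config(seed = 5, n_trials = 10)
  dy <- simulate_dyad(cfg)
  expect_equal(sum(dy$events$condition == "hand"), 10)
  expect_equal(sum(dy$events$condition == "foot"), 10)
  expect_equal(sum(dy$events$condition == "baseline"), 20)
  eps <- extract_epochs(dy$recording, dy$events, cfg$region_name,
                        conditions = c("hand", "foot"))
  expect_length(eps, 20)
  expect_true(all(vapply(eps, function(e) e$L, numeric(1)) == 204))
  expect_equal(dy$recording$fs, 10.17)
  # SDC channels present for both roles
  sdc <- dy$recording$channel_labels[dy$recording$region_map == "SDC"]
  expect_length(sdc, 2 * cfg$n_sdc)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_dyad(sim_config(seed = 77, n_trials = 2))
  b <- simulate_dyad(sim_config(seed = 77, n_trials = 2))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  c <- simulate_dyad(sim_config(seed = 78, n_trials = 2))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("cross-correlation peaks at the configured coupling lag", {
  cfg <- sim_config(seed = 12, n_trials = 6, coupling_lag = 2,
                    foot_extra_lag = 0, noise_sd = 0.1,
                    background_sd = 0.02, confounder_amplitude = 0,
                    n_channels_region = 1)
  dy <- simulate_dyad(cfg)
  m <- dy$recording$samples[, "M_M1_1"]
  i <- dy$recording$samples[, "I_M1_1"]
  cc <- ccf(m, i, lag.max = 10, plot = FALSE)
  # Imitator follows the Model by exactly coupling_lag samples
  expect_equal(cc$lag[which.max(cc$acf)], -2)
})

test_that("uncoupled dyads are labeled none and show no lagged coupling", {
  cfg <- sim_config(seed = 9, n_trials = 4, coupling_gain = 0,
                    n_channels_region = 1)
  dy <- simulate_dyad(cfg)
  expect_true(all(dy$truth$true_direction == "none"))
  ccs <- vapply(1:10, function(s) {
    d2 <- simulate_dyad(sim_config(seed = 200 + s, n_trials = 2,
                                   coupling_gain = 0, n_channels_region = 1,
                                   confounder_amplitude = 0))
    m <- d2$recording$samples[, "M_M1_1"]; i <- d2$recording$samples[, "I_M1_1"]
    cor(head(m, -2), tail(i, -2))
  }, numeric(1))
  expect_lt(abs(mean(ccs)), 3 * sd(ccs) / sqrt(length(ccs)))
})

test_that("task-component power is concentrated below 0.2 Hz", {
  cfg <- sim_config(seed = 3, n_trials = 6, noise_sd = 0,
                    background_sd = 0, confounder_amplitude = 0,
                    n_channels_region = 1)
  dy <- simulate_dyad(cfg)
  x <- dy$recording$samples[, "M_M1_1"]
  x <- x - mean(x)
  p <- abs(fft(x))^2
  f <- (seq_along(x) - 1) * cfg$fs / length(x)
  half <- f <= cfg$fs / 2
  expect_gt(sum(p[half & f < 0.2]) / sum(p[half]), 0.90)
})

test_that("datasets contain independent, reproducible dyads", {
  ds <- make_dataset(3, sim_config(n_trials = 2, n_channels_region = 1),
                     seed = 4)
  expect_length(ds, 3)
  expect_identical(vapply(ds, `[[`, character(1), "dyad_id"),
                   c("dyad01", "dyad02", "dyad03"))
  ds2 <- make_dataset(3, sim_config(n_trials = 2, n_channels_region = 1),
                      seed = 4)
  expect_identical(ds[[2]]$recording$samples, ds2[[2]]$recording$samples)
  # distinct dyads are essentially uncorrelated once the common task
  # schedule is removed (response_amplitude = 0 isolates the stochastic
  # parts; confounder phases and noise are per-dyad)
  ds0 <- make_dataset(2, sim_config(n_trials = 2, n_channels_region = 1,
                                    response_amplitude = 0), seed = 4)
  r <- abs(cor(ds0[[1]]$recording$samples[, 1],
               ds0[[2]]$recording$samples[, 1]))
  expect_lt(r, 0.2)
  # round-trip through the CSV dialect
  dir <- tempfile()
  write_dataset(ds, dir)
  rec <- read_recording(file.path(dir, "dyad01", "recording.csv"),
                        file.path(dir, "dyad01", "recording.yaml"))
  expect_identical(rec$samples, ds[[1]]$recording$samples)
})
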