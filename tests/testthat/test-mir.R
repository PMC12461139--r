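grid_default <- frequency_grid(10.17, 129)

test_that("independent subsystems have zero coupling at every frequency", {
  A1 <- rbind(cbind(matrix(c(0.5, 0.1, 0.2, 0.3), 2, 2), matrix(0, 2, 2)),
              cbind(matrix(0, 2, 2), matrix(c(0.4, -0.1, 0.1, 0.6), 2, 2)))
  Sigma <- diag(4); Sigma[1, 2] <- Sigma[2, 1] <- 0.3
  Sigma[3, 4] <- Sigma[4, 3] <- -0.2
  dec <- mir_decompose(var_to_state_space(var_model(A1, Sigma), fs = 10.17),
                       grid_default)
  expect_lt(max(abs(dec$f_total)), 1e-10)
  expect_lt(max(dec$f_M_to_I), 1e-10)
  expect_lt(max(dec$f_I_to_M), 1e-10)
  expect_lt(max(abs(dec$f_inst)), 1e-10)
})

test_that("three-way identity holds for random stable models", {
  for (seed in 1:25) {
    d <- sample(c(4, 6), 1)
    vm <- rand_stable_var(d, sample(1:2, 1), seed = 700 + seed)
    dec <- mir_decompose(var_to_state_space(vm, fs = 10.17), grid_default)
    resid <- max(abs(dec$f_total -
                       (dec$f_M_to_I + dec$f_I_to_M + dec$f_inst)))
    expect_lt(resid, 1e-8)
    expect_gte(min(dec$f_M_to_I), 0)   # clamped nonnegative
    expect_gte(min(dec$f_I_to_M), 0)
  }
})

test_that("directed spectra match the closed-form bivariate expression", {
  A1 <- matrix(c(0.9, 0, 0.16, 0.8), 2, 2, byrow = TRUE)
  ssm <- var_to_state_space(var_model(A1, diag(2)), fs = 10.17)
  dec <- mir_decompose(ssm, grid_default)
  oracle <- bivar_geweke_oracle(A1, 1, 1, grid_default$omega)
  expect_lt(max(abs(dec$f_M_to_I - oracle$f_M_to_I)), 1e-6)
  expect_lt(max(abs(dec$f_I_to_M - oracle$f_I_to_M)), 1e-6)
  # unidirectional coupling: no reverse flow, positive forward flow
  expect_lt(max(dec$f_I_to_M), 1e-10)
  expect_gt(max(dec$f_M_to_I), 0.01)
  cs <- causal_spectrum(dec)
  expect_gt(cs$C[which.max(dec$f_M_to_I)], 0)
})

test_that("causal spectrum is antisymmetric under role relabeling", {
  set.seed(42)
  ep <- white_epoch(seed = 42)
  # induce coupling so C is nonzero
  ep$data[, 3] <- ep$data[, 3] + 0.5 * c(0, 0, head(ep$data[, 1], -2))
  ep <- znormalize(ep)
  g <- frequency_grid(ep$fs, 129)
  dec_a <- mir_decompose(fit_epoch_ssm(ep), g)
  dec_b <- mir_decompose(fit_epoch_ssm(relabel_epoch(ep)), g)
  expect_equal(dec_b$f_M_to_I, dec_a$f_I_to_M, tolerance = 1e-10)
  expect_equal(causal_spectrum(dec_b)$C, -causal_spectrum(dec_a)$C,
               tolerance = 1e-10)
  bi_a <- band_integrate(causal_spectrum(dec_a), use_mask = FALSE)
  bi_b <- band_integrate(causal_spectrum(dec_b), use_mask = FALSE)
  expect_equal(bi_b$value, -bi_a$value, tolerance = 1e-12)
  expect_equal(bi_b$intensity, bi_a$intensity, tolerance = 1e-12)
})

test_that("a symmetric dyad has identically zero causal spectrum", {
  # block-symmetric model: swapping the two channels leaves it invariant
  A1 <- matrix(c(0.5, 0.2, 0.2, 0.5), 2, 2)
  Sigma <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  dec <- mir_decompose(var_to_state_space(var_model(A1, Sigma), fs = 10),
                       frequency_grid(10, 65))
  expect_lt(max(abs(causal_spectrum(dec)$C)), 1e-10)
})

test_that("band integration follows the 1/(4*pi) trapezoid contract", {
  fs <- 10.17
  g <- frequency_grid(fs, 513)
  dec <- structure(list(grid = g, f_total = rep(0, g$n),
                        f_M_to_I = rep(0.7, g$n), f_I_to_M = rep(0.2, g$n),
                        f_inst = rep(0, g$n)),
                   class = "spectral_decomposition")
  cs <- causal_spectrum(dec)
  expect_equal(band_integrate(cs, use_mask = FALSE)$value,
               0.5 * 2 * pi * (0.08 - 0.008) / fs / (4 * pi),
               tolerance = 1e-12)
  # zero integrand
  dec$f_M_to_I <- dec$f_I_to_M
  expect_equal(band_integrate(causal_spectrum(dec), use_mask = FALSE)$value, 0)
})

test_that("band integral converges under grid refinement", {
  vm <- rand_stable_var(4, 2, seed = 99)
  ssm <- var_to_state_space(vm, fs = 10.17)
  vals <- vapply(c(513L, 1025L, 2049L), function(n) {
    g <- frequency_grid(10.17, n)
    band_integrate(causal_spectrum(mir_decompose(ssm, g)),
                   use_mask = FALSE)$value
  }, numeric(1))
  expect_lt(abs(vals[2] - vals[3]) / max(abs(vals[3]), 1e-12), 1e-4)
  expect_lt(abs(vals[1] - vals[3]) / max(abs(vals[3]), 1e-12), 1e-3)
})

test_that("masked integration keeps only significant points per direction", {
  g <- frequency_grid(10, 11)
  cs <- structure(list(grid = g, C = rep(1, 11),
                       f_M_to_I = rep(1, 11), f_I_to_M = rep(0.5, 11),
                       mask_M_to_I = rep(c(TRUE, FALSE), length.out = 11),
                       mask_I_to_M = rep(FALSE, 11)),
                  class = "causal_spectrum")
  v_masked <- band_integrate(cs, band_hz = c(0.5, 4.5), use_mask = TRUE)$value
  v_open <- band_integrate(cs, band_hz = c(0.5, 4.5), use_mask = FALSE)$value
  expect_lt(v_masked, v_open)         # masking removed positive mass
  expect_gt(v_masked, 0)
  expect_error(band_integrate(causal_spectrum(structure(
    list(grid = g, f_total = rep(0, 11), f_M_to_I = rep(0, 11),
         f_I_to_M = rep(0, 11), f_inst = rep(0, 11)),
    class = "spectral_decomposition")), use_mask = TRUE), "masks")
})
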