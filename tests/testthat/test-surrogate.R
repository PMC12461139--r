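test_that("phase randomization preserves amplitude spectrum and mean", {
  for (L in c(204L, 205L)) {     # even and odd lengths
    set.seed(1)
    x <- matrix(rnorm(L * 3), L, 3)
    y <- phase_randomize(x, seed = 7)
    expect_equal(abs(mvfft(y)), abs(mvfft(x)), tolerance = 1e-10)
    expect_equal(colMeans(y), colMeans(x), tolerance = 1e-10)
    expect_true(is.numeric(y) && !is.complex(y))
  }
  expect_error(phase_randomize(matrix(complex(real = 1:8), 4, 2), 1),
               "real")
})

test_that("surrogates are reproducible and differ across seeds", {
  x <- matrix(rnorm(100 * 2), 100, 2)
  expect_identical(phase_randomize(x, 5), phase_randomize(x, 5))
  expect_false(identical(phase_randomize(x, 5), phase_randomize(x, 6)))
})

test_that("surrogate autocorrelation matches the original on average", {
  set.seed(3)
  # AR(1) series: nontrivial autocorrelation to preserve
  x <- as.numeric(stats::filter(rnorm(512), 0.8, method = "recursive"))
  ac0 <- acf(x, lag.max = 20, plot = FALSE)$acf[-1]
  acs <- sapply(1:50, function(s) {
    acf(phase_randomize(cbind(x), seed = s), lag.max = 20,
        plot = FALSE)$acf[-1]
  })
  se <- apply(acs, 1, sd) / sqrt(50)
  expect_true(all(abs(rowMeans(acs) - ac0) < 3 * pmax(se, 0.01)))
})

test_that("surrogates destroy cross-channel lag coupling", {
  set.seed(4)
  n <- 400
  drv <- rnorm(n)
  x <- cbind(drv, 0.9 * c(0, 0, head(drv, -2)) + 0.3 * rnorm(n))
  k <- 2
  ccf0 <- cor(x[1:(n - k), 1], x[(k + 1):n, 2])
  expect_gt(ccf0, 0.5)
  cc <- sapply(1:50, function(s) {
    y <- phase_randomize(x, seed = 100 + s)
    cor(y[1:(n - k), 1], y[(k + 1):n, 2])
  })
  expect_lt(abs(mean(cc)), 3 * sd(cc) / sqrt(50))
})

test_that("ensemble thresholds average the surrogate directed spectra", {
  ep <- white_epoch(L = 128, N = 1, seed = 9)
  g <- frequency_grid(ep$fs, 65)
  ens1 <- surrogate_threshold(ep, n_surrogates = 1, seed = 11, grid = g)
  expect_equal(ens1$mean_f_M_to_I, ens1$decompositions[[1]]$f_M_to_I)
  ens <- surrogate_threshold(ep, n_surrogates = 4, seed = 11, grid = g)
  m <- rowMeans(vapply(ens$decompositions, function(d) d$f_M_to_I,
                       numeric(g$n)))
  expect_equal(ens$mean_f_M_to_I, m)
  # determinism of the full ensemble
  ens_b <- surrogate_threshold(ep, n_surrogates = 4, seed = 11, grid = g)
  expect_identical(ens$mean_f_M_to_I, ens_b$mean_f_M_to_I)
})

test_that("significance masks compare observed spectra to thresholds", {
  ep <- white_epoch(L = 204, N = 1, seed = 15)
  g <- frequency_grid(ep$fs, 129)
  dec <- mir_decompose(fit_epoch_ssm(ep), g)
  ens <- surrogate_threshold(ep, n_surrogates = 5, seed = 2, grid = g)
  cs <- apply_significance(dec, ens)
  expect_identical(cs$mask_M_to_I, dec$f_M_to_I > ens$mean_f_M_to_I)
  # vacuous threshold: everything positive is significant
  ens0 <- ens
  ens0$mean_f_M_to_I <- rep(0, g$n); ens0$mean_f_I_to_M <- rep(0, g$n)
  cs0 <- apply_significance(dec, ens0)
  expect_identical(cs0$mask_M_to_I, dec$f_M_to_I > 0)
  # grid mismatch rejected
  ens_bad <- surrogate_threshold(ep, n_surrogates = 1, seed = 2,
                                 grid = frequency_grid(ep$fs, 65))
  expect_error(apply_significance(dec, ens_bad), "grid")
})

test_that("under the null the observed spectrum straddles the threshold", {
  # uncoupled white dyad: exceedance of the ensemble mean should be
  # neither rare nor dominant across frequencies and replicates
  rates <- vapply(1:12, function(r) {
    ep <- white_epoch(L = 204, N = 1, seed = 600 + r)
    g <- frequency_grid(ep$fs, 65)
    dec <- mir_decompose(fit_epoch_ssm(ep), g)
    ens <- surrogate_threshold(ep, n_surrogates = 10, seed = r, grid = g)
    mean(dec$f_M_to_I > ens$mean_f_M_to_I)
  }, numeric(1))
  expect_gt(mean(rates), 0.15)
  expect_lt(mean(rates), 0.85)
})

test_that("strong coupling is flagged significant across the band", {
  set.seed(8)
  n <- 204
  drv <- rnorm(n)
  dat <- cbind(drv + 0.1 * rnorm(n),
               c(0, 0, head(drv, -2)) + 0.1 * rnorm(n))
  ep <- znormalize(dyad_epoch(dat, 1, 10.17))
  g <- frequency_grid(10.17, 129)
  dec <- mir_decompose(fit_epoch_ssm(ep), g)
  ens <- surrogate_threshold(ep, n_surrogates = 10, seed = 3, grid = g)
  cs <- apply_significance(dec, ens)
  inband <- g$f >= 0.008 & g$f <= 0.08
  expect_gt(mean(cs$mask_M_to_I[inband]), 0.5)
})
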