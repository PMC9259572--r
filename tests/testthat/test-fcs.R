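test_that("a constant trace autocorrelates to exactly 1", {
  cur <- autocorrelate_multitau(rep(7, 2048), bin_width = 1e-3)
  expect_true(all(cur$G == 1))
  expect_error(autocorrelate_multitau(rep(0, 2048), bin_width = 1e-3),
               "zero mean")
  expect_error(autocorrelate_multitau(rpois(512, 5), bin_width = 1e-3),
               "2\\^10")
})

test_that("independent Poisson bins are uncorrelated at every lag", {
  set.seed(3)
  x <- rpois(2^13, 10)
  cur <- autocorrelate_multitau(x, bin_width = 1e-4)
  expect_lt(max(abs(cur$G - 1)), 0.02)
})

test_that("multi-tau agrees with brute-force correlation on every octave", {
  set.seed(13)
  n <- 2^14
  # an actually correlated signal: AR(1) intensity with Poisson counts
  lam <- stats::filter(rnorm(n, 0, 1), 0.97, method = "recursive")
  x <- rpois(n, exp(lam / 6) * 5)
  cur <- autocorrelate_multitau(x, bin_width = 1e-3, m = 16)

  # first octave: same native resolution
  direct <- autocorrelate_direct(x, 1:16)
  expect_equal(cur$G[1:16], direct, tolerance = 1e-10)

  # deeper octaves: brute-force on an independently rebinned trace
  x2 <- rebin2(x)
  d2 <- autocorrelate_direct(x2, 9:16)
  expect_equal(cur$G[17:24], d2, tolerance = 1e-10)
  x3 <- rebin2(x2)
  d3 <- autocorrelate_direct(x3, 9:16)
  expect_equal(cur$G[25:32], d3, tolerance = 1e-10)
})

test_that("diffusion-model fits round-trip a noiseless curve", {
  lag <- 10^seq(-5, 0, length.out = 60)
  G <- 1 + (1 / 5) / ((1 + lag / 2e-3) * sqrt(1 + 0.2^2 * lag / 2e-3))
  fit <- fit_fcs_model(list(lag = lag, G = G))
  expect_true(fit$converged)
  expect_equal(fit$N, 5, tolerance = 1e-6)
  expect_equal(fit$tau_d, 2e-3, tolerance = 1e-6)
  expect_equal(fit$s, 0.2, tolerance = 1e-4)
  # amplitude identity: fitted G(0) - 1 = 1/N
  expect_equal(smfretr:::fcs_model_g(0, fit$N, fit$tau_d, fit$s) - 1,
               1 / fit$N, tolerance = 1e-12)

  fit2 <- fit_fcs_model(list(lag = lag, G = G), fix_s = 0.2)
  expect_equal(fit2$tau_d, 2e-3, tolerance = 1e-8)
})

test_that("1% measurement noise leaves the diffusion time within 5%", {
  # lags span 50x tau_d, as a measured curve would; far beyond that the
  # curve is all baseline and carries no information on tau_d
  lag <- 10^seq(-5, -1, length.out = 60)
  G0 <- 1 + (1 / 5) / ((1 + lag / 2e-3) * sqrt(1 + 0.2^2 * lag / 2e-3))
  set.seed(99)

  errs <- replicate(50, {
    fit <- fit_fcs_model(list(lag = lag, G = G0 * (1 + rnorm(60, 0, 0.01))),
                         fix_s = 0.2)
    abs(fit$tau_d - 2e-3) / 2e-3
  })
  expect_lt(median(errs), 0.05)
})

test_that("Brownian simulation recovers tau_d = omega^2 / (4 D)", {
  # a 20 s trace holds ~3000 transits, so single-realization scatter is a
  # few percent; the median over three seeds tests the recovery property
  res <- sapply(1:3, function(s) {
    cfg <- cheap_fcs_config(seed = s, D = 1e-7, duration = 20)
    sim <- simulate_fcs_intensity(cfg)
    cur <- autocorrelate_multitau(sim$trace)
    fit <- fit_fcs_model(cur, fix_s = cfg$aspect_ratio, weights = 1 / cur$lag)
    expect_true(fit$converged)
    c(td = fit$tau_d / sim$truth$tau_d, N = fit$N / sim$truth$N)
  })
  expect_lt(abs(median(res["td", ]) - 1), 0.10)
  # correlation amplitude ~ 1/N
  expect_lt(abs(median(res["N", ]) - 1), 0.15)
})

test_that("doubling the occupancy halves the correlation amplitude", {
  amp <- sapply(c(2, 4), function(N) {
    cfg <- fcs_sim_config(1e-7, beam_waist = 0.5, aspect_ratio = 0.2,
                          mean_occupancy = N, brightness = 3e4,
                          duration = 15, time_step = 2e-4, box_size = 5,
                          seed = 7)
    sim <- simulate_fcs_intensity(cfg)
    cur <- autocorrelate_multitau(sim$trace)
    fit <- fit_fcs_model(cur, fix_s = 0.2, weights = 1 / cur$lag)
    1 / fit$N
  })
  expect_lt(abs(amp[1] / amp[2] - 2), 0.4)
})

test_that("diffusion and Stokes-Einstein conversions are exact closed forms", {
  expect_equal(diffusion_from_tau(2.25e-3, 0.3), 1.0e-7, tolerance = 1e-12)
  expect_equal(diffusion_from_tau(4.5e-3, 0.3), 0.5e-7, tolerance = 1e-12)
  # algebraic inverse of the simulator's tau_d = omega^2 / (4 D)
  D <- 1.27e-7
  expect_equal(diffusion_from_tau((0.3)^2 / (4 * D * 1e8), 0.3), D,
               tolerance = 1e-12)

  expect_lt(abs(radius_from_diffusion(1.0e-7, 294.15, 0.978e-3) - 22.0), 0.05)
  expect_equal(radius_from_diffusion(0.5e-7) / radius_from_diffusion(1e-7), 2,
               tolerance = 1e-12)
  expect_error(radius_from_diffusion(-1), "D")
})

test_that("percent radius change is the ratio identity with sign convention", {
  expect_equal(percent_radius_change(1e-7, 1e-7), 0)
  expect_equal(percent_radius_change(1.27, 0.98), 22.83465, tolerance = 1e-5)
  expect_equal(trunc(percent_radius_change(1.27e-7, 0.98e-7)), 22)
  # swapping arguments flips through the reciprocal ratio
  a <- percent_radius_change(1.27, 0.98)
  b <- percent_radius_change(0.98, 1.27)
  expect_lt(b, 0)
  expect_equal((1 - a / 100) * (1 - b / 100), 1, tolerance = 1e-12)
})

test_that("salt-screening fits interpolate two points and honour fix_b", {
  fit <- fit_salt_screening(c(0.137, 1.37), c(22, 4))
  b_closed <- log(22 / 4) / (sqrt(1.37) - sqrt(0.137))
  a_closed <- 22 * exp(b_closed * sqrt(0.137))
  expect_equal(fit$b, b_closed, tolerance = 1e-6)
  expect_equal(fit$a, a_closed, tolerance = 1e-6)
  expect_equal(as.numeric(fit$fitted), c(22, 4), tolerance = 1e-6)

  cfit <- fit_salt_screening(c(0.1, 0.5, 1), c(21, 22, 23), fix_b = 0)
  expect_equal(cfit$a, 22)
  expect_error(fit_salt_screening(0.1, 22), "distinct")
  expect_error(fit_salt_screening(c(-0.1, 1), c(5, 4)), "non-negative")
})
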