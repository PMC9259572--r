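test_that("simulation configs reject invariant violations with named bounds", {
  expect_error(smfret_sim_config(seed = NULL), "seed")
  expect_error(
    smfret_sim_config(true_lifetimes = data.frame(duration = 5, tau = 3),
                      acceptor_bleach_time = 5, donor_bleach_time = 4, seed = 1),
    "acceptor_bleach_time")
  expect_error(
    smfret_sim_config(true_lifetimes = data.frame(duration = 5, tau = 13),
                      seed = 1),
    "laser_period")
  expect_error(
    smfret_sim_config(donor_rate = -1,
                      true_lifetimes = data.frame(duration = 5, tau = 3),
                      seed = 1),
    "donor_rate")
  expect_error(fcs_sim_config(1e-7, aspect_ratio = 1.5, seed = 1), "aspect_ratio")
  expect_error(fcs_sim_config(1e-7, box_size = 1, seed = 1), "box_size")
  expect_error(fcs_sim_config(1e-7, time_step = 1e-2, seed = 1), "time_step")
  expect_error(generate_salt_series(22, 1, c(-0.1, 0.5)), "non-negative")
})

test_that("total donor photons match rate x time within 4 sigma", {
  # tau = tau_D makes the level rate equal the nominal donor rate
  cfg <- smfret_sim_config(
    donor_rate = 5000, background_rate = 0,
    true_lifetimes = data.frame(duration = 10, tau = 3.32),
    donor_bleach_time = 10.5, duration = 10.5, seed = 101)
  sim <- simulate_smfret_experiment(cfg)
  n_d <- sum(sim$stream$channel == "donor" & sim$stream$macrotime < 10)
  expect_lt(abs(n_d - 50000), 4 * sqrt(50000))
})

test_that("photon counts per window are Poisson at the configured rate", {
  cfg <- smfret_sim_config(
    donor_rate = 5000, background_rate = 0,
    true_lifetimes = data.frame(duration = 10, tau = 3.32),
    donor_bleach_time = 10.5, duration = 10.5, seed = 7)
  sim <- simulate_smfret_experiment(cfg)
  don <- sim$stream$macrotime[sim$stream$channel == "donor"]
  counts <- tabulate(floor(don[don < 10] / 0.1) + 1L, nbins = 100)
  lambda <- 5000 * 0.1
  x2 <- sum((counts - lambda)^2 / lambda)   # ~ chi^2 with 100 df
  expect_gt(x2, qchisq(0.005, df = 100))
  expect_lt(x2, qchisq(0.995, df = 100))
})

test_that("identical seeds reproduce streams bit-identically, different seeds differ", {
  cfg <- two_level_config(seed = 5)
  s1 <- simulate_smfret_experiment(cfg)$stream
  s2 <- simulate_smfret_experiment(cfg)$stream
  expect_identical(s1$macrotime, s2$macrotime)
  expect_identical(s1$microtime, s2$microtime)
  expect_identical(s1$channel, s2$channel)
  cfg2 <- two_level_config(seed = 6)
  s3 <- simulate_smfret_experiment(cfg2)$stream
  expect_false(length(s3) == length(s1))
})

test_that("microtime sampler obeys the compositional model", {
  # delta IRF, no background: unwrapped mean = IRF mean + tau
  irfd <- irf_delta(period = 400, n_bins = 8000)
  t1 <- sample_microtimes(1e5, 2, irfd, bg_fraction = 0, period = 400,
                          seed = 1, wrap = FALSE)
  se <- sd(t1) / sqrt(length(t1))
  expect_lt(abs(mean(t1) - (irf_mean(irfd) + 2)), 4 * se)

  # Gaussian IRF: additivity of means before wrapping
  irfg <- irf_gaussian(sigma = 0.2, center = 2, period = 400, n_bins = 8000)
  t2 <- sample_microtimes(1e5, 2, irfg, bg_fraction = 0, period = 400,
                          seed = 2, wrap = FALSE)
  se2 <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - (irf_mean(irfg) + 2)), 4 * se2)

  # pure background is uniform on [0, period)
  irf <- irf_gaussian()
  t3 <- sample_microtimes(5000, 2, irf, bg_fraction = 1, period = 12.5,
                          seed = 3)
  ks <- suppressWarnings(ks.test(t3, "punif", 0, 12.5))
  expect_gt(ks$p.value, 0.01)

  expect_error(sample_microtimes(0, 2, irf), "n")
  expect_error(sample_microtimes(10, Inf, irf), "tau")
  expect_error(sample_microtimes(10, 13, irf, period = 12.5), "tau")
})

test_that("FCS trace mean intensity matches background + brightness * N / 2^1.5", {
  cfg <- cheap_fcs_config(seed = 11, duration = 20)
  sim <- simulate_fcs_intensity(cfg)
  obs <- mean(sim$trace$counts) / cfg$time_step
  expect_lt(abs(obs / sim$truth$mean_rate - 1), 0.05)
})

test_that("pure background FCS traces are flat at G = 1", {
  cfg <- fcs_sim_config(1e-7, beam_waist = 0.5, aspect_ratio = 0.2,
                        mean_occupancy = 1, brightness = 1e-9,
                        background_rate = 1e4, duration = 8,
                        time_step = 2e-4, box_size = 5, seed = 21)
  sim <- simulate_fcs_intensity(cfg)
  cur <- autocorrelate_multitau(sim$trace)
  expect_lt(max(abs(cur$G - 1)), 0.02)
})

test_that("salt series generator evaluates the screening model", {
  s0 <- generate_salt_series(22, 0, c(0.01, 0.137, 1.37))
  expect_equal(s0$delta_R_pct, rep(22, 3))
  s1 <- generate_salt_series(48.40, 2.130, 0.137)
  expect_equal(s1$delta_R_pct, 22.0, tolerance = 1e-3)
})

test_that("noisy salt series fits recover the generating parameters", {
  conc <- c(0.01, 0.05, 0.137, 0.3, 0.6, 0.9, 1.1, 1.37)
  ser <- generate_salt_series(48.4, 2.13, conc, noise_sd = 1, seed = 1)
  fit <- fit_salt_screening(ser$concentration_M, ser$delta_R_pct)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 48.4), 2 * fit$se[["a"]])
  expect_lt(abs(fit$b - 2.13), 2 * fit$se[["b"]])
})
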