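test_that("bunching floors to full bunches, preserves order, warns when short", {
  mt <- seq_len(3500) / 1000
  b <- bunch_photons(mt, 1000)
  expect_length(b, 3)
  expect_identical(b[[1]]$microtime, mt[1:1000])
  expect_identical(b[[3]]$microtime, mt[2001:3000])
  # disjoint and order-preserving: concatenation is a prefix of the input
  expect_identical(unlist(lapply(b, `[[`, "microtime")), mt[1:3000])
  expect_warning(b0 <- bunch_photons(mt[1:999], 1000), "999")
  expect_length(b0, 0)
  expect_error(bunch_photons(mt, 50), "bunch_size")
})

test_that("MLE reduces to the analytic exponential mean in the delta-IRF limit", {
  irfd <- irf_delta(period = 200, n_bins = 20000)
  est <- fit_lifetime_mle(rep(c(1, 2, 3), 40), irfd, bg_fraction = 0,
                          laser_period = 200)
  expect_lt(abs(est$tau - 2.0), 0.02)
  expect_false(est$flagged)
})

test_that("MLE recovers a simulated lifetime within its own standard error", {
  irf <- irf_gaussian(sigma = 0.15)
  mt <- sample_microtimes(1000, 2.5, irf, bg_fraction = 0.05, seed = 11)
  est <- fit_lifetime_mle(mt, irf, bg_fraction = 0.05)
  expect_false(est$flagged)
  expect_lt(abs(est$tau - 2.5), 3 * est$se)
  expect_true(is.finite(est$loglik))
})

test_that("every fit is a local optimum of its own likelihood", {
  irf <- irf_gaussian()
  set.seed(17)
  for (tau in c(0.8, 1.5, 2.5, 3.3)) {
    mt <- sample_microtimes(1000, tau, irf, bg_fraction = 0.05)
    est <- fit_lifetime_mle(mt, irf, bg_fraction = 0.05)
    ll <- function(tt) {
      p <- smfretr:::decay_model_probs(tt, irf, 0.05)
      h <- tabulate(pmin(floor(mt / irf$resolution),
                         length(irf$counts) - 1) + 1,
                    nbins = length(irf$counts))
      sum(h[h > 0] * log(p[h > 0]))
    }
    expect_gte(ll(est$tau), ll(est$tau * 1.1))
    expect_gte(ll(est$tau), ll(est$tau * 0.9))
  }
})

test_that("degenerate pure-background bunches are flagged, not accepted", {
  irf <- irf_gaussian()
  set.seed(23)
  mt <- runif(1000, 0, 12.5)           # pure background
  est <- fit_lifetime_mle(mt, irf, bg_fraction = 0.05)
  expect_true(est$flagged)
})

test_that("lifetime distributions use the square-root bin rule and raw quantiles", {
  set.seed(5)
  d <- build_lifetime_distribution(rnorm(900, 2.5, 0.1), label = "x")
  expect_equal(d$n_bins, 30)
  expect_equal(length(d$counts), 30)
  expect_equal(sum(d$counts), 900)
  expect_equal(d$median, median(d$tau))

  d1 <- build_lifetime_distribution(2.0)
  expect_equal(d1$n_bins, 1)
  expect_equal(d1$median, 2.0)

  # flagged estimates are excluded by default
  df <- data.frame(tau = c(2, 2.1, 9), flagged = c(FALSE, FALSE, TRUE))
  d2 <- build_lifetime_distribution(df)
  expect_equal(d2$n, 2)
  expect_error(build_lifetime_distribution(df[df$tau > 10, ]), "no")
})

test_that("a two-lifetime mixture yields a bimodal distribution with median between modes", {
  irf <- irf_gaussian()
  set.seed(29)
  taus <- c(
    vapply(1:40, function(i) fit_lifetime_mle(
      sample_microtimes(1000, 3.0, irf, 0.05), irf, 0.05)$tau, numeric(1)),
    vapply(1:40, function(i) fit_lifetime_mle(
      sample_microtimes(1000, 1.5, irf, 0.05), irf, 0.05)$tau, numeric(1)))
  d <- build_lifetime_distribution(taus, label = "mixture")
  mids <- (d$breaks[-1] + d$breaks[-length(d$breaks)]) / 2
  lo <- d$counts[mids < 1.8]
  hi <- d$counts[mids > 2.7]
  valley <- d$counts[mids >= 1.8 & mids <= 2.7]
  expect_gt(max(lo), max(valley))      # two populated modes, empty middle
  expect_gt(max(hi), max(valley))
  expect_gt(d$median, 1.5)
  expect_lt(d$median, 3.0)
})

test_that("one-way ANOVA matches hand computation and flags at P <= 0.001", {
  a <- compare_distributions_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a$F, 13.5)
  expect_equal(c(a$df1, a$df2), c(1L, 4L))
  expect_false(a$significant)          # p ~ 0.021 > 0.001

  same <- compare_distributions_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)

  degen <- compare_distributions_anova(list(c(2, 2), c(2, 2)))
  expect_true(is.na(degen$F))

  expect_error(compare_distributions_anova(list(1, c(1, 2))), "at least 2")
})

test_that("ANOVA type-I error at the 0.001 flag is calibrated", {
  set.seed(1234)
  hits <- sum(replicate(2000, {
    g <- list(rnorm(30, 2.5, 0.1), rnorm(30, 2.5, 0.1))
    compare_distributions_anova(g)$significant
  }))
  # Binomial(2000, 0.001): P(X > 8) < 1e-5
  expect_lte(hits, 8)
})
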