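test_that("binning uses the half-open convention and exact counts", {
  s <- photon_stream(c(0.05, 0.15, 0.16), c(1, 1, 1), rep("donor", 3))
  tr <- bin_photons(s, 0.1)
  expect_equal(unname(tr$counts[, "donor"]), c(1, 2))

  # a photon exactly on a bin edge lands in the later bin
  s2 <- photon_stream(0.2, 1, "donor")
  tr2 <- bin_photons(s2, 0.1)
  expect_equal(unname(tr2$counts[, "donor"]), c(0, 0, 1))

  expect_error(bin_photons(photon_stream(numeric(0), numeric(0),
                                         character(0)), 0.1), "empty")
})

test_that("a Poisson stream bins to the configured mean rate", {
  cfg <- smfret_sim_config(
    donor_rate = 5000, background_rate = 0,
    true_lifetimes = data.frame(duration = 10, tau = 3.32),
    donor_bleach_time = 10.5, duration = 10.5, seed = 55)
  sim <- simulate_smfret_experiment(cfg)
  tr <- bin_photons(sim$stream, 0.1, duration = 10)
  m <- mean(tr$counts[, "donor"])
  expect_lt(abs(m - 500), 4 * sqrt(500 / 100))
})

test_that("change-point detection finds steps and leaves constants whole", {
  set.seed(2)
  flat <- rpois(200, 50)
  seg <- detect_change_points(make_trace(flat), alpha = 0.01)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$rate, sum(flat) / 200)

  set.seed(3)
  x <- c(rpois(100, 50), rpois(100, 5))
  seg2 <- detect_change_points(make_trace(x), alpha = 0.01)
  expect_equal(nrow(seg2), 2)
  expect_lt(abs((seg2$end_bin[1] - 1) - 100), 2)      # boundary at bin 100 +/- 1

  set.seed(4)
  y <- c(rpois(120, 50), rpois(120, 25), rpois(120, 2))
  seg3 <- detect_change_points(make_trace(y), alpha = 0.01)
  expect_equal(nrow(seg3), 3)
  for (i in 1:3) {
    truth <- c(50, 25, 2)[i]
    se <- sqrt(truth / seg3$n_bins[i])
    expect_lt(abs(seg3$rate[i] - truth), 2.5 * se)
  }
  expect_error(detect_change_points(c(1.5, 2, 2, 2)), "integer")
})

test_that("segment rates are exact and segmentation is idempotent", {
  set.seed(9)
  x <- c(rpois(80, 40), rpois(80, 8))
  tr <- make_trace(x)
  seg <- detect_change_points(tr, alpha = 0.01)
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start_bin[i]:(seg$end_bin[i] - 1)
    expect_identical(seg$rate[i], sum(x[idx]) / length(idx))
    # re-running on a returned segment yields no further splits
    if (length(idx) >= 4) {
      sub <- detect_change_points(make_trace(x[idx]), alpha = 0.01)
      expect_equal(nrow(sub), 1)
    }
  }
})

test_that("bleach steps are downward boundaries landing at background", {
  seg1 <- detect_change_points(make_trace(c(rep(50L, 60), rep(1L, 60))))
  st1 <- classify_bleach_steps(seg1, background_rate = 1)
  expect_equal(st1$n_steps, 1)
  expect_equal(st1$steps$boundary_bin, 60)

  # 50 -> 25 is a level change, not a bleach; only 25 -> 1 reaches background
  seg2 <- detect_change_points(
    make_trace(c(rep(50L, 60), rep(25L, 60), rep(1L, 60))))
  st2 <- classify_bleach_steps(seg2, background_rate = 1)
  expect_equal(st2$n_steps, 1)

  seg3 <- detect_change_points(make_trace(rep(30L, 80)))
  expect_equal(classify_bleach_steps(seg3, 1)$n_steps, 0)
  expect_error(classify_bleach_steps(seg3, -1), "background_rate")
})

test_that("single-pair selection accepts exactly one bleach step per channel", {
  cfg <- smfret_sim_config(
    true_lifetimes = data.frame(duration = 4, tau = 2.5),
    acceptor_bleach_time = 4, donor_bleach_time = 9, duration = 11,
    seed = 31)
  sim <- simulate_smfret_experiment(cfg)
  tr <- bin_photons(sim$stream, 0.1, duration = cfg$duration)
  dec <- select_single_pair_trace(tr, background = cfg$background_rate * 0.1)
  expect_true(dec$accepted)
  expect_equal(dec$reason, "ok")
  expect_lt(abs(dec$acceptor_bleach_time - 4), 0.25)
  expect_lt(abs(dec$donor_bleach_time - 9), 0.25)

  # two apparent acceptor bleach events -> rejected
  set.seed(41)
  donor <- c(rpois(60, 50), rpois(40, 2))
  acceptor <- c(rpois(25, 50), rpois(20, 2), rpois(15, 40), rpois(40, 2))
  dec2 <- select_single_pair_trace(make_trace(donor, acceptor),
                                   background = 2)
  expect_false(dec2$accepted)
  expect_equal(dec2$reason, "multiple_acceptor_steps")

  # acceptor never above background -> no bleach to find
  set.seed(42)
  dec3 <- select_single_pair_trace(
    make_trace(c(rpois(60, 50), rpois(40, 2)), rpois(100, 2)),
    background = 2)
  expect_false(dec3$accepted)
  expect_equal(dec3$reason, "no_acceptor_bleach")

  dec4 <- select_single_pair_trace(make_trace(rep(1L, 50), rep(1L, 50)),
                                   background = 1)
  expect_false(dec4$accepted)
  expect_equal(dec4$reason, "too_few_photons")
})

test_that("FRET levels partition pre-bleach donor photons at segment bounds", {
  cfg <- two_level_config(seed = 7, tau = c(3.0, 1.5), dur = c(3, 5),
                          donor_bleach = 12)
  sim <- simulate_smfret_experiment(cfg)
  tr <- bin_photons(sim$stream, 0.1, duration = cfg$duration)
  dec <- select_single_pair_trace(tr, background = cfg$background_rate * 0.1)
  expect_true(dec$accepted)
  lv <- extract_fret_levels(sim$stream, dec$segments$donor,
                            dec$acceptor_bleach_time, dec$donor_bleach_time)
  expect_length(lv$levels, 2)
  expect_lt(abs(lv$levels[[2]]$start - 3), 0.1 + 1e-9)

  # levels partition the pre-bleach donor photons exactly
  pre <- sum(sim$stream$channel == "donor" &
               sim$stream$macrotime < dec$acceptor_bleach_time)
  expect_equal(sum(vapply(lv$levels, function(l) length(l$microtime),
                          integer(1))), pre)
  # donor-only photons live between the bleaches
  expect_true(all(lv$donor_only$macrotime >= dec$acceptor_bleach_time))
  expect_true(all(lv$donor_only$macrotime < dec$donor_bleach_time))

  expect_error(extract_fret_levels(sim$stream, dec$segments$donor, 99),
               "outside")
})
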