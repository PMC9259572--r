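#' Configuration for a simulated smFRET acquisition
#'
#' Describes one immobilized donor/acceptor pair probed until photobleaching:
#' piecewise-constant FRET levels (each with its own donor lifetime), a fixed
#' acceptor and donor photobleaching time, and uniform-microtime background
#' in both channels. Bleach times are fixed inputs so a given seed fully
#' determines the stream; see [smfret_sim_config_random_bleach()] for the
#' sampled-bleach convenience wrapper.
#'
#' The donor count rate during a FRET level scales with the level's quantum
#' yield: `donor_rate * tau / donor_only_lifetime`, with `donor_rate` the
#' unquenched (donor-only) rate that is recovered after acceptor bleaching.
#' That scaling is what gives level boundaries and the acceptor bleach an
#' intensity signature the change-point stage can detect.
#'
#' @param donor_rate Unquenched donor detection rate, photons/s.
#' @param acceptor_rate Acceptor detection rate during FRET, photons/s.
#' @param background_rate Background rate per channel, photons/s.
#' @param true_lifetimes Data frame (or list of `c(duration, tau)`) giving
#'   each FRET level's duration (s) and donor lifetime tau_DA (ns), in order.
#' @param donor_only_lifetime Donor-only lifetime tau_D, ns.
#' @param irf An [irf_histogram()]; default Gaussian, sigma 0.15 ns.
#' @param laser_period Laser period, ns (12.5 ns = 80 MHz).
#' @param acceptor_bleach_time Acceptor bleach time, s; default the summed
#'   level durations. Must precede `donor_bleach_time`.
#' @param donor_bleach_time Donor bleach time, s.
#' @param duration Total acquisition, s; default `donor_bleach_time + 2`.
#' @param bin_width Intensity binning used downstream, s.
#' @param seed Mandatory integer seed; there is no hidden entropy.
#' @return A validated list of class `smfret_sim_config`.
#' @export
smfret_sim_config <- function(donor_rate = 5000, acceptor_rate = 5000,
                              background_rate = 200,
                              true_lifetimes = data.frame(duration = 10, tau = 3.0),
                              donor_only_lifetime = 3.32,
                              irf = irf_gaussian(period = laser_period),
                              laser_period = 12.5,
                              acceptor_bleach_time = NULL,
                              donor_bleach_time = NULL,
                              duration = NULL,
                              bin_width = 0.1,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  if (is.list(true_lifetimes) && !is.data.frame(true_lifetimes))
    true_lifetimes <- as.data.frame(do.call(rbind, true_lifetimes)) |>
      stats::setNames(c("duration", "tau"))
  stopifnot(is.data.frame(true_lifetimes),
            all(c("duration", "tau") %in% names(true_lifetimes)),
            nrow(true_lifetimes) >= 1)
  check_nonneg(donor_rate, "donor_rate")
  check_nonneg(acceptor_rate, "acceptor_rate")
  check_nonneg(background_rate, "background_rate")
  check_positive(donor_only_lifetime, "donor_only_lifetime")
  check_positive(laser_period, "laser_period")
  check_positive(bin_width, "bin_width")
  check_positive(true_lifetimes$duration, "true_lifetimes$duration")
  if (any(true_lifetimes$tau <= 0) || any(true_lifetimes$tau >= laser_period))
    abort("every tau_DA must lie in (0, laser_period = %.4g) ns", laser_period)
  if (donor_only_lifetime >= laser_period)
    abort("donor_only_lifetime must be < laser_period")
  stopifnot(inherits(irf, "irf_histogram"))
  if (abs(irf$period - laser_period) > 1e-9)
    abort("IRF period (%.4g ns) does not match laser_period (%.4g ns)",
          irf$period, laser_period)
  total_levels <- sum(true_lifetimes$duration)
  acceptor_bleach_time <- acceptor_bleach_time %||% total_levels
  check_positive(acceptor_bleach_time, "acceptor_bleach_time")
  if (acceptor_bleach_time > total_levels + 1e-12)
    abort("acceptor_bleach_time (%.4g s) exceeds the summed level durations (%.4g s)",
          acceptor_bleach_time, total_levels)
  donor_bleach_time <- donor_bleach_time %||% (acceptor_bleach_time + 5)
  check_positive(donor_bleach_time, "donor_bleach_time")
  if (acceptor_bleach_time >= donor_bleach_time)
    abort("acceptor_bleach_time (%.4g s) must precede donor_bleach_time (%.4g s)",
          acceptor_bleach_time, donor_bleach_time)
  duration <- duration %||% (donor_bleach_time + 2)
  if (duration < donor_bleach_time)
    abort("duration must not be shorter than donor_bleach_time")
  structure(
    list(donor_rate = donor_rate, acceptor_rate = acceptor_rate,
         background_rate = background_rate, true_lifetimes = true_lifetimes,
         donor_only_lifetime = donor_only_lifetime, irf = irf,
         laser_period = laser_period,
         acceptor_bleach_time = acceptor_bleach_time,
         donor_bleach_time = donor_bleach_time, duration = duration,
         bin_width = bin_width, seed = as.integer(seed)),
    class = "smfret_sim_config")
}

#' Sample bleach times, then build an smFRET simulation config
#'
#' Convenience wrapper that draws exponential acceptor/donor bleach times
#' (conditioned so the acceptor bleaches first, inside the level schedule)
#' and delegates to [smfret_sim_config()].
#'
#' @param mean_acceptor_bleach,mean_donor_survival Means (s) of the
#'   exponential bleach-time draws; donor survival is measured from the
#'   acceptor bleach.
#' @param seed Integer seed used both for the draws and the photon stream.
#' @param ... Passed on to [smfret_sim_config()].
#' @return An `smfret_sim_config`.
#' @export
smfret_sim_config_random_bleach <- function(mean_acceptor_bleach = 5,
                                            mean_donor_survival = 5,
                                            seed, ...) {
  if (missing(seed)) abort("`seed` is mandatory")
  set.seed(as.integer(seed))
  args <- list(...)
  lv <- args$true_lifetimes %||% data.frame(duration = 10, tau = 3.0)
  if (is.list(lv) && !is.data.frame(lv))
    lv <- stats::setNames(as.data.frame(do.call(rbind, lv)), c("duration", "tau"))
  total <- sum(lv$duration)
  ab <- min(stats::rexp(1, 1 / mean_acceptor_bleach) + 0.5, total)
  db <- ab + stats::rexp(1, 1 / mean_donor_survival) + 0.5
  do.call(smfret_sim_config,
          c(list(acceptor_bleach_time = ab, donor_bleach_time = db,
                 seed = seed), args))
}

#' Sample TCSPC microtimes from the IRF-convolved decay model
#'
#' Composes an IRF arrival offset with an exponential decay delay, wraps the
#' sum on the laser period, and replaces a `bg_fraction` of draws with
#' uniform background. This is the exact generative inverse of the model
#' that [fit_lifetime_mle()] maximizes.
#'
#' @param n Number of photons (>= 1).
#' @param tau Decay lifetime, ns, in (0, period).
#' @param irf An [irf_histogram()].
#' @param bg_fraction Probability in \[0, 1\] that a photon is background.
#' @param period Laser period, ns.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @param wrap If `FALSE`, return the unwrapped IRF + decay delays
#'   (diagnostic use; background draws are still uniform on the period).
#' @return Numeric vector of microtimes, in \[0, period) when wrapped.
#' @export
sample_microtimes <- function(n, tau, irf, bg_fraction = 0, period = 12.5,
                              seed = NULL, wrap = TRUE) {
  if (n < 1) abort("`n` must be >= 1")
  if (!is.finite(tau) || tau <= 0 || tau >= period)
    abort("`tau` must be finite and in (0, period = %.4g)", period)
  stopifnot(inherits(irf, "irf_histogram"))
  if (bg_fraction < 0 || bg_fraction > 1) abort("`bg_fraction` must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- sample_irf(irf, n) + stats::rexp(n, rate = 1 / tau)
  if (wrap) t <- t %% period
  if (bg_fraction > 0) {
    bg <- stats::runif(n) < bg_fraction
    t[bg] <- stats::runif(sum(bg), 0, period)
  }
  t
}

# Homogeneous Poisson arrivals on [t0, t1) at `rate` /s (sorted).
poisson_arrivals <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate one immobilized smFRET molecule
#'
#' Generates a two-channel photon stream with piecewise-constant Poisson
#' rates: donor signal photons carry IRF-convolved exponential microtimes at
#' the active level's lifetime (the donor-only lifetime after acceptor
#' bleaching), background photons carry uniform microtimes, and the acceptor
#' channel goes dark at the acceptor bleach. Acceptor microtimes are drawn
#' uniform: the pipeline never analyzes them.
#'
#' @param config An [smfret_sim_config()].
#' @return List with `stream` (a [photon_stream()]) and `truth` (level
#'   boundaries and lifetimes, bleach times, per-piece rates).
#' @export
simulate_smfret_experiment <- function(config) {
  stopifnot(inherits(config, "smfret_sim_config"))
  set.seed(config$seed)
  ab <- config$acceptor_bleach_time
  db <- config$donor_bleach_time
  dur <- config$duration
  tauD <- config$donor_only_lifetime
  # donor signal pieces: FRET levels clipped at the acceptor bleach, then
  # a donor-only piece up to the donor bleach
  lv <- config$true_lifetimes
  bounds <- c(0, cumsum(lv$duration))
  pieces <- data.frame(start = pmin(bounds[-length(bounds)], ab),
                       end = pmin(bounds[-1], ab), tau = lv$tau)
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
  pieces <- rbind(pieces, data.frame(start = ab, end = db, tau = tauD))
  pieces$rate <- config$donor_rate * pieces$tau / tauD

  d_time <- numeric(0); d_micro <- numeric(0)
  for (i in seq_len(nrow(pieces))) {
    tt <- poisson_arrivals(pieces$rate[i], pieces$start[i], pieces$end[i])
    if (length(tt) > 0) {
      mm <- sample_microtimes(length(tt), pieces$tau[i], config$irf,
                              bg_fraction = 0, period = config$laser_period)
      d_time <- c(d_time, tt); d_micro <- c(d_micro, mm)
    }
  }
  # background, both channels, whole acquisition
  bgd <- poisson_arrivals(config$background_rate, 0, dur)
  d_time <- c(d_time, bgd)
  d_micro <- c(d_micro, stats::runif(length(bgd), 0, config$laser_period))

  a_time <- c(poisson_arrivals(config$acceptor_rate, 0, ab),
              poisson_arrivals(config$background_rate, 0, dur))
  a_micro <- stats::runif(length(a_time), 0, config$laser_period)

  time <- c(d_time, a_time)
  micro <- c(d_micro, a_micro)
  chan <- rep(c("donor", "acceptor"), c(length(d_time), length(a_time)))
  ord <- order(time)

  stream <- photon_stream(time[ord], micro[ord], chan[ord],
                          laser_period = config$laser_period,
                          metadata = list(simulated = TRUE, seed = config$seed))
  truth <- list(level_bounds = c(pmin(bounds, ab)[!duplicated(pmin(bounds, ab))]),
                level_tau = pieces$tau[pieces$end <= ab + 1e-12],
                donor_only_lifetime = tauD,
                acceptor_bleach_time = ab, donor_bleach_time = db,
                duration = dur, pieces = pieces,
                background_rate = config$background_rate)
  list(stream = stream, truth = truth)
}
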