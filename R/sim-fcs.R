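#' Configuration for a Brownian-dynamics FCS simulation
#'
#' Point emitters diffuse in a periodic box through a 3D Gaussian confocal
#' detection volume; the detected intensity is binned into `time_step`
#' intervals with Poisson shot noise. The number of emitters is set so that
#' the mean occupancy of the effective confocal volume
#' `V_eff = pi^(3/2) * omega^2 * (omega/s)` equals `mean_occupancy`.
#'
#' @param diffusion_coefficient D, cm^2/s.
#' @param beam_waist Transversal 1/e^2 beam waist omega, micrometres.
#' @param aspect_ratio s, transversal/axial dimension ratio, in (0, 1\].
#' @param mean_occupancy Target mean number of emitters in `V_eff`.
#' @param brightness Detected photons/s per molecule at the focus center.
#' @param background_rate Uncorrelated background, photons/s.
#' @param duration Trace length, s.
#' @param time_step Sampling interval, s; must satisfy
#'   `sqrt(4 D dt) < omega / 5` so a step stays well inside the focus.
#' @param box_size Periodic box edge in x and y, micrometres
#'   (>= 10 * omega).
#' @param box_size_z Periodic box extent along the optical axis,
#'   micrometres; defaults to at least three axial waists so the
#'   finite-box correlation plateau stays negligible against the axial
#'   profile, which is much wider than the transversal one.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `fcs_sim_config`.
#' @export
fcs_sim_config <- function(diffusion_coefficient, beam_waist = 0.3,
                           aspect_ratio = 0.2, mean_occupancy = 2,
                           brightness = 3e4, background_rate = 0,
                           duration = 60, time_step = 5e-5,
                           box_size = 12 * beam_waist,
                           box_size_z = max(box_size,
                                            3 * beam_waist / aspect_ratio),
                           seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  check_positive(diffusion_coefficient, "diffusion_coefficient")
  check_positive(beam_waist, "beam_waist")
  if (aspect_ratio <= 0 || aspect_ratio > 1)
    abort("`aspect_ratio` must satisfy 0 < s <= 1")
  check_positive(mean_occupancy, "mean_occupancy")
  check_positive(brightness, "brightness")
  check_nonneg(background_rate, "background_rate")
  check_positive(duration, "duration")
  check_positive(time_step, "time_step")
  if (box_size < 10 * beam_waist)
    abort("box_size (%.4g um) must be >= 10 * beam_waist (%.4g um)",
          box_size, 10 * beam_waist)
  if (box_size_z < 2 * beam_waist / aspect_ratio)
    abort("box_size_z (%.4g um) must be >= 2 axial waists (%.4g um)",
          box_size_z, 2 * beam_waist / aspect_ratio)
  D_um <- diffusion_coefficient * 1e8      # cm^2/s -> um^2/s
  step_rms <- sqrt(4 * D_um * time_step)
  if (step_rms >= beam_waist / 5)
    abort("time_step too coarse: sqrt(4 D dt) = %.4g um must be < omega/5 = %.4g um",
          step_rms, beam_waist / 5)
  structure(
    list(diffusion_coefficient = diffusion_coefficient,
         beam_waist = beam_waist, aspect_ratio = aspect_ratio,
         mean_occupancy = mean_occupancy, brightness = brightness,
         background_rate = background_rate, duration = duration,
         time_step = time_step, box_size = box_size,
         box_size_z = box_size_z, seed = as.integer(seed)),
    class = "fcs_sim_config")
}

#' Simulate an FCS intensity trace by Brownian dynamics
#'
#' Each emitter performs independent Gaussian steps of standard deviation
#' `sqrt(2 D dt)` per axis in a periodic box centered on the focus; the
#' instantaneous detection rate is the Gaussian confocal profile summed over
#' emitters plus background, and per-step photon counts are Poisson. The
#' trace is binned counts (not individual photons): the multi-tau
#' correlator consumes binned counts directly.
#'
#' @param config An [fcs_sim_config()].
#' @return List with `trace` (an [intensity_trace()], one `intensity`
#'   channel) and `truth` (`D` cm^2/s, `tau_d = omega^2/(4 D)` seconds,
#'   effective occupancy `N`, emitter count, mean-rate prediction).
#' @export
simulate_fcs_intensity <- function(config) {
  stopifnot(inherits(config, "fcs_sim_config"))
  set.seed(config$seed)
  dt <- config$time_step
  n_steps <- round(config$duration / dt)
  L <- config$box_size
  Lz <- config$box_size_z
  w <- config$beam_waist
  wz <- w / config$aspect_ratio
  D_um <- config$diffusion_coefficient * 1e8
  sd_step <- sqrt(2 * D_um * dt)
  v_box <- L^2 * Lz
  v_eff <- pi^1.5 * w^2 * wz
  n_emit <- max(1L, round(config$mean_occupancy * v_box / v_eff))
  n_eff <- n_emit * v_eff / v_box   # realized occupancy after rounding

  rate <- rep(config$background_rate, n_steps)
  for (i in seq_len(n_emit)) {
    x <- stats::runif(1, -L / 2, L / 2) + cumsum(stats::rnorm(n_steps, 0, sd_step))
    y <- stats::runif(1, -L / 2, L / 2) + cumsum(stats::rnorm(n_steps, 0, sd_step))
    z <- stats::runif(1, -Lz / 2, Lz / 2) + cumsum(stats::rnorm(n_steps, 0, sd_step))
    x <- x - L * round(x / L)
    y <- y - L * round(y / L)
    z <- z - Lz * round(z / Lz)
    rate <- rate + config$brightness *
      exp(-2 * (x * x + y * y) / w^2 - 2 * (z * z) / wz^2)
  }
  counts <- stats::rpois(n_steps, rate * dt)
  trace <- intensity_trace(matrix(counts, ncol = 1,
                                  dimnames = list(NULL, "intensity")),
                           bin_width = dt)
  # the box truncates the Gaussian detection profile (matters in z, where
  # the box edge is only ~1 axial waist away); erf factors per axis
  erf <- function(u) 2 * stats::pnorm(u * sqrt(2)) - 1
  trunc_fac <- erf(sqrt(2) * (L / 2) / w)^2 * erf(sqrt(2) * (Lz / 2) / wz)
  truth <- list(D = config$diffusion_coefficient,
                tau_d = w^2 / (4 * D_um),
                N = n_eff, n_emitters = n_emit,
                mean_rate = config$background_rate +
                  config$brightness * n_eff * trunc_fac / 2^1.5)
  list(trace = trace, truth = truth)
}
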