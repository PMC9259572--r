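#' Run the full smFRET analysis pipeline on simulated conditions
#'
#' For each condition, simulates `n_molecules` immobilized molecules
#' (per-molecule sub-seeds derived from the single global seed by a counter
#' scheme, so adding molecules never perturbs earlier streams), then runs
#' the full chain: 100-ms binning, change-point segmentation, single-pair
#' selection, FRET-level extraction, 1000-photon bunching, bunch-wise MLE
#' lifetime fitting, efficiency/distance conversion, per-condition lifetime
#' distributions, and one-way ANOVA across conditions.
#'
#' @param conditions List of conditions; each a list with `label`,
#'   `n_molecules`, and `sim` (an [smfret_sim_config()] whose seed is
#'   overwritten per molecule).
#' @param seed Global integer seed.
#' @param bunch_size Photons per lifetime bunch.
#' @param alpha Change-point significance.
#' @param calibration A [fret_calibration()].
#' @param min_photons Minimum photons for a usable molecule.
#' @param out_dir Optional directory; when given, writes `bunches.csv`,
#'   `decisions.csv`, `distributions.csv` and `manifest.json`.
#' @return List of class `smfret_run`: `bunches` (per-bunch table with tau,
#'   se, flag, E, r), `decisions` (per-molecule), `distributions` (one
#'   [build_lifetime_distribution()] per condition with >= 1 bunch),
#'   `anova` (when >= 2 conditions have bunches), `manifest`.
#' @export
run_smfret_pipeline <- function(conditions, seed, bunch_size = 1000,
                                alpha = 0.01,
                                calibration = fret_calibration(),
                                min_photons = 1000, out_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  for (cond in conditions) {
    if (is.null(cond$label) || is.null(cond$n_molecules) ||
        !inherits(cond$sim, "smfret_sim_config"))
      abort("each condition needs `label`, `n_molecules` and a `sim` config")
  }
  n_total <- sum(vapply(conditions, `[[`, numeric(1), "n_molecules"))
  seeds <- derive_seeds(seed, n_total)

  decisions <- list(); bunch_rows <- list()
  idx <- 0L
  for (cond in conditions) {
    for (mol in seq_len(cond$n_molecules)) {
      idx <- idx + 1L
      cfg <- cond$sim
      cfg$seed <- seeds[idx]
      sim <- simulate_smfret_experiment(cfg)
      trace <- bin_photons(sim$stream, cfg$bin_width, duration = cfg$duration)
      bg_bin <- cfg$background_rate * cfg$bin_width
      dec <- select_single_pair_trace(trace, background = bg_bin,
                                      alpha = alpha,
                                      min_photons = min_photons)
      decisions[[idx]] <- data.frame(
        condition = cond$label, molecule = mol, seed = seeds[idx],
        accepted = dec$accepted, reason = dec$reason,
        acceptor_bleach_time = dec$acceptor_bleach_time,
        donor_bleach_time = dec$donor_bleach_time)
      if (!dec$accepted) next

      lv <- extract_fret_levels(sim$stream, dec$segments$donor,
                                dec$acceptor_bleach_time,
                                dec$donor_bleach_time)
      for (li in seq_along(lv$levels)) {
        level <- lv$levels[[li]]
        if (length(level$microtime) < bunch_size) next
        bunches <- bunch_photons(level, bunch_size)
        for (bi in seq_along(bunches)) {
          b <- bunches[[bi]]
          f_bg <- min(0.95, cfg$background_rate * b$time_span / b$n)
          est <- fit_lifetime_mle(b, cfg$irf, bg_fraction = f_bg,
                                  laser_period = cfg$laser_period)
          bunch_rows[[length(bunch_rows) + 1L]] <- data.frame(
            condition = cond$label, molecule = mol, level = li, bunch = bi,
            tau = est$tau, se = est$se, bg_fraction = f_bg,
            flag = est$flag, flagged = est$flagged)
        }
      }
    }
  }
  decisions <- do.call(rbind, decisions)
  bunches <- if (length(bunch_rows) > 0) do.call(rbind, bunch_rows) else
    data.frame(condition = character(0), molecule = integer(0),
               level = integer(0), bunch = integer(0), tau = numeric(0),
               se = numeric(0), bg_fraction = numeric(0),
               flag = character(0), flagged = logical(0))

  # lifetimes -> efficiencies and distances (flagged bunches get NA)
  if (nrow(bunches) > 0) {
    fr <- distance_from_lifetime(bunches$tau, calibration)
    bunches$E <- ifelse(bunches$flagged, NA_real_, fr$E)
    bunches$r_nm <- ifelse(bunches$flagged, NA_real_, fr$r_nm)
  } else {
    bunches$E <- numeric(0); bunches$r_nm <- numeric(0)
  }

  labels <- vapply(conditions, `[[`, character(1), "label")
  distributions <- list()
  for (lb in labels) {
    taus <- bunches$tau[bunches$condition == lb & !bunches$flagged]
    if (length(taus) > 0)
      distributions[[lb]] <- build_lifetime_distribution(taus, label = lb)
  }
  anova <- NULL
  if (length(distributions) >= 2)
    anova <- compare_distributions_anova(lapply(distributions, `[[`, "tau"))

  manifest <- list(
    seed = seed,
    conditions = labels,
    molecules_in = nrow(decisions),
    accepted = sum(decisions$accepted),
    rejected_reasons = table(decisions$reason[!decisions$accepted]),
    n_bunches = nrow(bunches),
    n_flagged = sum(bunches$flagged),
    bunch_size = bunch_size, alpha = alpha,
    calibration = unclass(calibration),
    version = as.character(utils::packageVersion("smfretr")))
  if (manifest$accepted == 0)
    message("0 accepted molecules; outputs are empty")

  res <- structure(list(bunches = bunches, decisions = decisions,
                        distributions = distributions, anova = anova,
                        manifest = manifest),
                   class = "smfret_run")
  if (!is.null(out_dir)) write_smfret_run(res, out_dir)
  res
}

# serialize an smfret_run to plain CSV/JSON under out_dir
write_smfret_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(res$bunches, file.path(out_dir, "bunches.csv"))
  write_results_table(res$decisions, file.path(out_dir, "decisions.csv"))
  dist_df <- do.call(rbind, lapply(res$distributions, function(d)
    data.frame(condition = d$label, n_bunches = d$n, n_bins = d$n_bins,
               median = d$median, q1 = d$q1, q3 = d$q3)))
  if (!is.null(dist_df))
    write_results_table(dist_df, file.path(out_dir, "distributions.csv"))
  man <- res$manifest
  man$rejected_reasons <- as.list(man$rejected_reasons)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.smfret_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("smfret_run: %d molecules in, %d accepted, %d bunches (%d flagged)\n",
              m$molecules_in, m$accepted, m$n_bunches, m$n_flagged))
  for (d in x$distributions)
    cat(sprintf("  %s: median tau %.3f ns (n = %d)\n", d$label, d$median, d$n))
  if (!is.null(x$anova))
    cat(sprintf("  ANOVA: F = %.3g on (%d, %d) df, P = %.3g\n",
                x$anova$F, x$anova$df1, x$anova$df2, x$anova$p))
  invisible(x)
}

#' Run the FCS analysis pipeline on simulated conditions
#'
#' For each condition: Brownian-dynamics simulation, multi-tau
#' autocorrelation, diffusion-model fit (with the aspect ratio fixed at
#' the simulation's calibration value by default), then
#' `D = omega^2 / (4 tau_d)` and the Stokes-Einstein radius. When a
#' `compare = c(with, without)` pair of labels is given, the percent radius
#' change between those conditions is reported.
#'
#' @param conditions List of conditions; each a list with `label` and
#'   `sim` (an [fcs_sim_config()], seed overwritten from the global seed).
#' @param seed Global integer seed.
#' @param m Multi-tau lags per octave.
#' @param fix_s Fix the aspect ratio in the fit to the simulated value
#'   (default `TRUE`; set `FALSE` to fit it).
#' @param temperature,viscosity Stokes-Einstein inputs (K, Pa s).
#' @param compare Optional `c(with, without)` labels for the radius-change
#'   comparison.
#' @param salt Optional data frame with `concentration_M`, `delta_R_pct`
#'   to fit the Debye-Hueckel screening model.
#' @param out_dir Optional output directory (`fcs_fits.csv`,
#'   `manifest.json`).
#' @return List of class `fcs_run`: `fits` (per-condition table with N,
#'   tau_d, D, R), `curves`, `delta_r_pct` (when compared), `salt_fit`,
#'   `manifest`.
#' @export
run_fcs_pipeline <- function(conditions, seed, m = 16, fix_s = TRUE,
                             temperature = 294.15, viscosity = 0.978e-3,
                             compare = NULL, salt = NULL, out_dir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  for (cond in conditions) {
    if (is.null(cond$label) || !inherits(cond$sim, "fcs_sim_config"))
      abort("each condition needs `label` and a `sim` config")
  }
  seeds <- derive_seeds(seed, length(conditions))
  rows <- list(); curves <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    cfg <- cond$sim
    cfg$seed <- seeds[i]
    sim <- simulate_fcs_intensity(cfg)
    curve <- autocorrelate_multitau(sim$trace, m = m)
    # correlator variance grows ~ lag/duration, so weight lags by 1/lag;
    # otherwise the dense, noisy long-lag baseline dominates the residuals
    fit <- fit_fcs_model(curve,
                         fix_s = if (isTRUE(fix_s)) cfg$aspect_ratio else NULL,
                         weights = 1 / curve$lag)
    if (!isTRUE(fit$converged))
      abort("FCS fit failed for condition '%s': %s", cond$label, fit$message)
    D <- diffusion_from_tau(fit$tau_d, cfg$beam_waist)
    R <- radius_from_diffusion(D, temperature, viscosity)
    curves[[cond$label]] <- curve
    rows[[i]] <- data.frame(
      condition = cond$label, seed = seeds[i], N = fit$N, tau_d = fit$tau_d,
      s = fit$s, D_cm2_s = D, R_nm = R,
      true_D = cfg$diffusion_coefficient, true_tau_d = sim$truth$tau_d,
      true_N = sim$truth$N)
  }
  fits <- do.call(rbind, rows)

  delta_r <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, all(compare %in% fits$condition))
    Dw <- fits$D_cm2_s[fits$condition == compare[1]]
    Dwo <- fits$D_cm2_s[fits$condition == compare[2]]
    delta_r <- percent_radius_change(Dw, Dwo)
  }
  salt_fit <- NULL
  if (!is.null(salt))
    salt_fit <- fit_salt_screening(salt$concentration_M, salt$delta_R_pct)

  manifest <- list(seed = seed, conditions = fits$condition,
                   m = m, fix_s = fix_s,
                   temperature_K = temperature, viscosity_Pa_s = viscosity,
                   delta_r_pct = delta_r,
                   version = as.character(utils::packageVersion("smfretr")))
  res <- structure(list(fits = fits, curves = curves,
                        delta_r_pct = delta_r, salt_fit = salt_fit,
                        manifest = manifest),
                   class = "fcs_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(fits, file.path(out_dir, "fcs_fits.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.fcs_run <- function(x, ...) {
  for (i in seq_len(nrow(x$fits)))
    cat(sprintf("  %s: tau_d = %.3g ms, D = %.3g cm^2/s, R = %.1f nm\n",
                x$fits$condition[i], 1e3 * x$fits$tau_d[i],
                x$fits$D_cm2_s[i], x$fits$R_nm[i]))
  if (!is.null(x$delta_r_pct))
    cat(sprintf("  radius change: %.1f%%\n", x$delta_r_pct))
  invisible(x)
}
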