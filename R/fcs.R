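#' Multi-tau autocorrelation of an intensity trace
#'
#' Normalized autocorrelation `G(tau) = <I(t) I(t+tau)> / <I>^2` on a
#' quasi-logarithmic lag grid: `m` linear lags at the native resolution,
#' then `m/2` further lags per octave after rebinning the counts by 2.
#' Symmetric normalization is used against finite-trace bias: the product
#' mean at lag k is divided by the means of the leading and trailing
#' subtraces separately.
#'
#' @param trace An [intensity_trace()] (single channel, >= 2^10 bins) or a
#'   bare counts vector with `bin_width` supplied.
#' @param m Lags per octave (even, >= 4; default 16).
#' @param bin_width Bin width in s when `trace` is a bare vector.
#' @param channel Channel column when the trace has several.
#' @return Object of class `fcs_curve`: data frame fields `lag` (s), `G`,
#'   `n_samples`, plus `mean_intensity` (counts/bin at native resolution)
#'   and `bin_width`.
#' @export
autocorrelate_multitau <- function(trace, m = 16, bin_width = NULL,
                                   channel = NULL) {
  if (inherits(trace, "intensity_trace")) {
    channel <- channel %||% colnames(trace$counts)[1]
    x <- as.numeric(trace$counts[, channel])
    bin_width <- trace$bin_width
  } else {
    x <- as.numeric(trace)
    if (is.null(bin_width)) abort("`bin_width` required for a bare vector")
  }
  if (m < 4 || m %% 2 != 0) abort("`m` must be an even number >= 4")
  if (length(x) < 2^10) abort("trace must have at least 2^10 bins")
  if (mean(x) == 0) abort("trace has zero mean intensity")
  mean_native <- mean(x)

  lag <- numeric(0); G <- numeric(0); n_samples <- integer(0)
  level <- 0L
  repeat {
    n <- length(x)
    ks <- if (level == 0L) seq_len(m) else (m %/% 2 + 1L):m
    for (k in ks) {
      if (k >= n - 1L) break
      a <- x[1:(n - k)]
      b <- x[(k + 1):n]
      lag <- c(lag, k * bin_width * 2^level)
      G <- c(G, mean(a * b) / (mean(a) * mean(b)))
      n_samples <- c(n_samples, n - k)
    }
    n2 <- n %/% 2L
    if (n2 < 2L * m) break
    x <- x[seq_len(2L * n2)]
    x <- x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]
    level <- level + 1L
  }
  structure(list(lag = lag, G = G, n_samples = n_samples,
                 mean_intensity = mean_native, bin_width = bin_width),
            class = "fcs_curve")
}

#' Direct (brute-force) autocorrelation at chosen lags
#'
#' Plain O(n * n_lags) evaluation of the same symmetric-normalized
#' estimator as [autocorrelate_multitau()], on an explicit list of lags in
#' bins; intended as an independent cross-check on short traces.
#'
#' @param x Counts vector.
#' @param lags_bins Integer lags, in bins (>= 1).
#' @return Numeric vector of G values.
#' @export
autocorrelate_direct <- function(x, lags_bins) {
  x <- as.numeric(x)
  n <- length(x)
  vapply(lags_bins, function(k) {
    if (k >= n - 1) return(NA_real_)
    s_ab <- 0; s_a <- 0; s_b <- 0
    for (i in 1:(n - k)) {            # deliberately naive
      s_ab <- s_ab + x[i] * x[i + k]
      s_a <- s_a + x[i]
      s_b <- s_b + x[i + k]
    }
    (s_ab / (n - k)) / ((s_a / (n - k)) * (s_b / (n - k)))
  }, numeric(1))
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("fcs_curve: %d lags from %.3g to %.3g s, G(min lag) = %.4f\n",
              length(x$lag), min(x$lag), max(x$lag), x$G[1]))
  invisible(x)
}

# Single-species 3D translational diffusion model:
# G(tau) = 1 + (1/N) / ((1 + tau/tau_d) * sqrt(1 + s^2 tau/tau_d))
fcs_model_g <- function(tau, N, tau_d, s) {
  1 + (1 / N) / ((1 + tau / tau_d) * sqrt(1 + s^2 * tau / tau_d))
}

#' Fit the one-species diffusion model to an FCS curve
#'
#' Least-squares fit of `G(tau) = 1 + (1/N) / ((1 + tau/tau_d) *
#' sqrt(1 + s^2 tau/tau_d))` by Levenberg-Marquardt. The amplitude
#' satisfies `G(0) - 1 = 1/N` by model structure. `s` (the
#' transversal/axial aspect ratio) and `N` are weakly identifiable on
#' noisy curves, so `s` can be fixed from an instrument calibration via
#' `fix_s`. Non-convergence is reported in the `converged` flag and
#' message, never silently.
#'
#' @param curve An [fcs_curve()] (or list with `lag` and `G`).
#' @param init Optional named list of starting values (`N`, `tau_d`, `s`);
#'   defaults are derived from the curve.
#' @param fix_s Optional fixed aspect ratio in (0, 1\].
#' @param weights Optional per-lag weights (default uniform).
#' @return Object of class `fcs_fit`: `N`, `tau_d` (s), `s`, `cov`,
#'   `resid_norm`, `converged`, `message`, `fitted`.
#' @export
fit_fcs_model <- function(curve, init = NULL, fix_s = NULL, weights = NULL) {
  lag <- curve$lag
  G <- curve$G
  if (length(lag) < 4) abort("need at least 4 lags to fit")
  if (any(!is.finite(G))) abort("non-finite G values")
  amp0 <- max(mean(G[seq_len(min(3, length(G)))]) - 1, 1e-4)
  N0 <- 1 / amp0
  half <- which(G - 1 <= amp0 / 2)
  td0 <- if (length(half) > 0) max(lag[half[1]], lag[1]) else stats::median(lag)
  s0 <- 0.2
  if (!is.null(init)) {
    N0 <- init$N %||% N0; td0 <- init$tau_d %||% td0; s0 <- init$s %||% s0
  }
  w <- weights %||% rep(1, length(lag))
  df <- data.frame(lag = lag, G = G, w = w)

  fit <- tryCatch({
    if (is.null(fix_s)) {
      minpack.lm::nlsLM(
        G ~ 1 + (1 / N) / ((1 + lag / tau_d) * sqrt(1 + s^2 * lag / tau_d)),
        data = df, weights = w,
        start = list(N = N0, tau_d = td0, s = s0),
        lower = c(N = 1e-6, tau_d = 1e-9, s = 1e-4),
        upper = c(N = Inf, tau_d = Inf, s = 1),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      if (fix_s <= 0 || fix_s > 1) abort("`fix_s` must be in (0, 1]")
      s_fixed <- fix_s
      minpack.lm::nlsLM(
        G ~ 1 + (1 / N) / ((1 + lag / tau_d) * sqrt(1 + s_fixed^2 * lag / tau_d)),
        data = df, weights = w,
        start = list(N = N0, tau_d = td0),
        lower = c(N = 1e-6, tau_d = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(N = NA_real_, tau_d = NA_real_, s = fix_s %||% NA_real_,
                          cov = NULL, resid_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit), fitted = NULL),
                     class = "fcs_fit"))
  cf <- stats::coef(fit)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(
    list(N = unname(cf["N"]), tau_d = unname(cf["tau_d"]),
         s = if (is.null(fix_s)) unname(cf["s"]) else fix_s,
         cov = cv, resid_norm = sqrt(sum(stats::resid(fit)^2)),
         converged = fit$convInfo$isConv,
         message = fit$convInfo$stopMessage, fitted = stats::fitted(fit)),
    class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("fcs_fit: N = %.3f, tau_d = %.4g s, s = %.3f (%s)\n",
              x$N, x$tau_d, x$s,
              if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Diffusion coefficient from the FCS residence time
#'
#' `D = omega^2 / (4 tau_d)`, with the beam waist in micrometres converted
#' to cm so D comes out in cm^2/s.
#'
#' @param tau_d Mean residence (diffusion) time, s (> 0).
#' @param omega Beam waist, micrometres (> 0).
#' @return D in cm^2/s.
#' @export
diffusion_from_tau <- function(tau_d, omega) {
  check_positive(tau_d, "tau_d")
  check_positive(omega, "omega")
  (omega * 1e-4)^2 / (4 * tau_d)
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' `R = k_B T / (6 pi eta D)`. Defaults are room temperature (21 degrees C,
#' 294.15 K) and the viscosity of water at that temperature.
#'
#' @param D Diffusion coefficient, cm^2/s (> 0).
#' @param temperature Temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Hydrodynamic radius in nm.
#' @export
radius_from_diffusion <- function(D, temperature = 294.15,
                                  viscosity = 0.978e-3) {
  check_positive(D, "D")
  check_positive(temperature, "temperature")
  check_positive(viscosity, "viscosity")
  kB <- 1.380649e-23
  R_m <- kB * temperature / (6 * pi * viscosity * (D * 1e-4))
  R_m * 1e9
}

#' Percent change in hydrodynamic radius between two conditions
#'
#' `dR = 100 * (1 - R_with / R_without) = 100 * (1 - D_without / D_with)`;
#' positive values mean compaction in the "with" condition. Temperature and
#' viscosity cancel.
#'
#' @param D_with,D_without Diffusion coefficients (same units, > 0).
#' @return Percent radius change.
#' @export
percent_radius_change <- function(D_with, D_without) {
  check_positive(D_with, "D_with")
  check_positive(D_without, "D_without")
  100 * (1 - D_without / D_with)
}

#' Fit the Debye-Hueckel salt-screening model
#'
#' Nonlinear least squares for `dR(c) = a * exp(-b * sqrt(c))`. With
#' exactly two points the fit interpolates them (the closed-form two-point
#' solution). `fix_b` constrains the screening coefficient, in which case
#' the amplitude has the weighted closed form
#' `a = sum(dR * e) / sum(e^2)` with `e = exp(-b sqrt(c))`.
#'
#' @param concentrations Salt concentrations, mol/L (>= 0, >= 2 distinct).
#' @param delta_r Percent radius changes.
#' @param fix_b Optional fixed screening coefficient.
#' @return Object of class `salt_screen_fit`: `a` (%), `b` (1/sqrt(M)),
#'   `se` (named, `NA` with zero residual degrees of freedom), `cov`,
#'   `fitted`, `converged`.
#' @export
fit_salt_screening <- function(concentrations, delta_r, fix_b = NULL) {
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    abort("concentrations must be non-negative")
  if (length(concentrations) != length(delta_r))
    abort("concentrations and delta_r must have equal length")
  if (length(unique(concentrations)) < 2)
    abort("need at least 2 distinct concentrations")
  sq <- sqrt(concentrations)
  if (!is.null(fix_b)) {
    e <- exp(-fix_b * sq)
    a <- sum(delta_r * e) / sum(e^2)
    return(structure(list(a = a, b = fix_b, se = c(a = NA_real_, b = NA_real_),
                          cov = NULL, fitted = a * e, converged = TRUE),
                     class = "salt_screen_fit"))
  }
  # log-linear start when all responses are positive, else crude fallback
  pos <- delta_r > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(delta_r[pos]) ~ sq[pos])
    b0 <- max(-unname(stats::coef(lf)[2]), 1e-3)
    a0 <- exp(unname(stats::coef(lf)[1]))
  } else {
    a0 <- max(delta_r, 1); b0 <- 1
  }
  df <- data.frame(sq = sq, dr = delta_r)
  fit <- minpack.lm::nlsLM(dr ~ a * exp(-b * sq), data = df,
                           start = list(a = a0, b = b0),
                           lower = c(a = 0, b = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  dfres <- stats::df.residual(fit)
  se <- if (dfres > 0) {
    sm <- summary(fit)
    stats::setNames(sm$coefficients[, "Std. Error"], names(cf))
  } else c(a = NA_real_, b = NA_real_)
  cv <- if (dfres > 0) tryCatch(stats::vcov(fit), error = function(e) NULL)
        else NULL
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), se = se,
                 cov = cv, fitted = stats::fitted(fit),
                 converged = fit$convInfo$isConv),
            class = "salt_screen_fit")
}

#' @export
print.salt_screen_fit <- function(x, ...) {
  cat(sprintf("salt_screen_fit: dR(c) = %.3f * exp(-%.4f sqrt(c)) %%\n",
              x$a, x$b))
  invisible(x)
}
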