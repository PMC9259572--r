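#' Generate a synthetic salt-screening series
#'
#' Evaluates the Debye-Hueckel screening model
#' `dR(c) = a * exp(-b * sqrt(c))` on the given salt concentrations and adds
#' Gaussian noise, for testing [fit_salt_screening()].
#'
#' @param a Amplitude, percent radius change at zero salt.
#' @param b Screening coefficient, 1/sqrt(M).
#' @param concentrations Salt concentrations, mol/L (non-negative).
#' @param noise_sd Gaussian noise standard deviation, percentage points.
#' @param seed Optional integer seed.
#' @return Data frame with columns `concentration_M` and `delta_R_pct`.
#' @export
generate_salt_series <- function(a, b, concentrations, noise_sd = 0,
                                 seed = NULL) {
  check_nonneg(a, "a")
  check_nonneg(b, "b")
  check_nonneg(noise_sd, "noise_sd")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    abort("concentrations must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  dr <- a * exp(-b * sqrt(concentrations))
  if (noise_sd > 0) dr <- dr + stats::rnorm(length(dr), 0, noise_sd)
  data.frame(concentration_M = concentrations, delta_R_pct = dr)
}
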