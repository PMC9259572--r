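#' FRET calibration constants
#'
#' Foerster distance and donor-only reference lifetime for the dye pair.
#' Defaults are for the snap-surface-594 / Cy5 pair: r0 = 8.49 nm and
#' tau_D = 3.32 ns.
#'
#' @param r0 Foerster distance, nm (> 0).
#' @param tau_d Donor-only lifetime, ns (> 0).
#' @return List of class `fret_calibration`.
#' @export
fret_calibration <- function(r0 = 8.49, tau_d = 3.32) {
  check_positive(r0, "r0")
  check_positive(tau_d, "tau_d")
  structure(list(r0 = r0, tau_d = tau_d), class = "fret_calibration")
}

#' FRET efficiency from the donor lifetime
#'
#' `E = 1 - tau_DA / tau_D`. A quenched donor (tau_DA < tau_D) gives
#' E in (0, 1); tau_DA >= tau_D yields E <= 0, which is physically a
#' donor-only observation and is returned as-is so callers can flag it
#' (see [distance_from_lifetime()]).
#'
#' @param tau_da Donor lifetime in the presence of the acceptor, ns (> 0).
#' @param tau_d Donor-only lifetime, ns (> 0). Vectorized over `tau_da`.
#' @return FRET efficiency (dimensionless).
#' @export
efficiency_from_lifetime <- function(tau_da, tau_d = 3.32) {
  check_positive(tau_da, "tau_da")
  check_positive(tau_d, "tau_d")
  1 - tau_da / tau_d
}

#' Donor-acceptor distance from the FRET efficiency
#'
#' `r = r0 * ((1 - E) / E)^(1/6)`; strictly decreasing in E, with
#' `r(0.5) = r0`.
#'
#' @param E FRET efficiency, each value in (0, 1).
#' @param calibration A [fret_calibration()].
#' @return Distance r in nm.
#' @export
distance_from_efficiency <- function(E, calibration = fret_calibration()) {
  stopifnot(inherits(calibration, "fret_calibration"))
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    abort("E must lie strictly inside (0, 1)")
  calibration$r0 * ((1 - E) / E)^(1 / 6)
}

#' Efficiency from a donor-acceptor distance
#'
#' Algebraic inverse of [distance_from_efficiency()]:
#' `E = 1 / (1 + (r/r0)^6)`.
#'
#' @param r Distance, nm (> 0).
#' @param calibration A [fret_calibration()].
#' @return FRET efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, calibration = fret_calibration()) {
  stopifnot(inherits(calibration, "fret_calibration"))
  check_positive(r, "r")
  1 / (1 + (r / calibration$r0)^6)
}

#' Donor-acceptor distance directly from the donor lifetime
#'
#' Composition of the efficiency and distance relations. Lifetimes at or
#' above the donor-only reference give non-positive efficiencies; these are
#' flagged out-of-range (`valid = FALSE`, `r = NA`) rather than clipped, so
#' donor-only bunches stay auditable.
#'
#' @param tau_da Donor lifetime(s), ns.
#' @param calibration A [fret_calibration()].
#' @return Data frame with columns `tau_da`, `E`, `r_nm`, `r_nm_rounded`
#'   (nearest nm, for comparison with printed values) and `valid`.
#' @export
distance_from_lifetime <- function(tau_da, calibration = fret_calibration()) {
  stopifnot(inherits(calibration, "fret_calibration"))
  E <- efficiency_from_lifetime(tau_da, calibration$tau_d)
  valid <- E > 0 & E < 1
  r <- rep(NA_real_, length(E))
  r[valid] <- distance_from_efficiency(E[valid], calibration)
  data.frame(tau_da = tau_da, E = E, r_nm = r,
             r_nm_rounded = round(r), valid = valid)
}
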