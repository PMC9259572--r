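#' Instrument response function histogram
#'
#' A TCSPC instrument response function (IRF) stored as a histogram on a
#' uniform microtime grid spanning one full laser period. The grid is shared
#' by the decay model, so counts outside the measured support are simply
#' zero bins.
#'
#' @param counts Non-negative counts per bin; length defines the grid.
#' @param period Laser period in ns (12.5 ns for 80 MHz repetition).
#' @return An object of class `irf_histogram` with fields `counts`,
#'   `period`, `resolution` (ns/bin) and `edges` (bin edges, ns).
#' @export
irf_histogram <- function(counts, period = 12.5) {
  check_positive(period, "period")
  if (length(counts) < 2L) abort("IRF needs at least 2 bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("IRF counts must be non-negative and finite")
  if (sum(counts) <= 0) abort("IRF has zero total counts")
  resolution <- period / length(counts)
  structure(
    list(counts = as.numeric(counts), period = period,
         resolution = resolution,
         edges = seq(0, period, by = resolution)),
    class = "irf_histogram")
}

#' @export
print.irf_histogram <- function(x, ...) {
  cat(sprintf("IRF histogram: %d bins x %.4g ns over a %.4g ns period (mean %.3f ns)\n",
              length(x$counts), x$resolution, x$period, irf_mean(x)))
  invisible(x)
}

#' Synthetic Gaussian IRF
#'
#' Discretizes a Gaussian timing response onto the TCSPC grid. Used as the
#' default instrument response when no measured histogram is supplied;
#' sigma = 0.15 ns is typical for a single-photon avalanche diode.
#'
#' @param sigma Gaussian width in ns.
#' @param center Peak position in ns (must leave the tails inside the period).
#' @param period Laser period, ns.
#' @param n_bins Number of grid bins.
#' @param total Approximate total counts used to quantize the histogram.
#' @return An [irf_histogram()].
#' @export
irf_gaussian <- function(sigma = 0.15, center = 1.5, period = 12.5,
                         n_bins = 256, total = 1e6) {
  check_positive(sigma, "sigma")
  centers <- (seq_len(n_bins) - 0.5) * period / n_bins
  dens <- stats::dnorm(centers, mean = center, sd = sigma)
  counts <- round(dens / sum(dens) * total)
  if (sum(counts) <= 0) abort("IRF discretization collapsed; widen sigma or grid")
  irf_histogram(counts, period = period)
}

#' Idealized delta-function IRF
#'
#' All counts in the single bin containing `at`; useful for tests where the
#' analytic exponential limit must hold.
#'
#' @param period Laser period, ns.
#' @param n_bins Number of grid bins.
#' @param at Position of the delta, ns.
#' @return An [irf_histogram()].
#' @export
irf_delta <- function(period = 12.5, n_bins = 256, at = 0) {
  counts <- numeric(n_bins)
  j <- min(floor(at / (period / n_bins)), n_bins - 1) + 1
  counts[j] <- 1e6
  irf_histogram(counts, period = period)
}

#' Mean of an IRF histogram
#'
#' Expectation of a draw from [sample_irf()]: bin centers weighted by counts
#' (within-bin positions are uniform).
#'
#' @param irf An [irf_histogram()].
#' @return Mean arrival offset in ns.
#' @export
irf_mean <- function(irf) {
  stopifnot(inherits(irf, "irf_histogram"))
  centers <- (seq_along(irf$counts) - 0.5) * irf$resolution
  sum(centers * irf$counts) / sum(irf$counts)
}

#' Draw arrival-time offsets from an IRF histogram
#'
#' Samples a bin proportionally to its counts, then a uniform position
#' within the bin.
#'
#' @param irf An [irf_histogram()].
#' @param n Number of draws.
#' @return Numeric vector of offsets in ns, in \[0, period).
#' @export
sample_irf <- function(irf, n) {
  stopifnot(inherits(irf, "irf_histogram"), n >= 0)
  if (n == 0) return(numeric(0))
  bins <- sample.int(length(irf$counts), n, replace = TRUE, prob = irf$counts)
  (bins - 1 + stats::runif(n)) * irf$resolution
}
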