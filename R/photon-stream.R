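#' Time-tagged two-channel photon stream
#'
#' Container for one molecule's (or one FCS acquisition's) photon records:
#' absolute arrival time (macrotime, seconds), delay after the excitation
#' pulse (microtime, ns) and detection channel. Validation rejects rather
#' than repairs: unsorted macrotimes, out-of-period microtimes or unknown
#' channel codes are errors.
#'
#' @param macrotime Non-decreasing arrival times, seconds.
#' @param microtime Pulse delays in ns, each in \[0, laser_period).
#' @param channel Character or factor, values `"donor"` / `"acceptor"`.
#' @param laser_period Laser period in ns.
#' @param metadata Named list (acquisition id, condition label, ...).
#' @return Object of class `photon_stream`.
#' @export
photon_stream <- function(macrotime, microtime, channel,
                          laser_period = 12.5, metadata = list()) {
  check_positive(laser_period, "laser_period")
  n <- length(macrotime)
  if (length(microtime) != n || length(channel) != n)
    abort("macrotime, microtime and channel must have equal length")
  if (n > 0) {
    if (any(!is.finite(macrotime)) || is.unsorted(macrotime))
      abort("macrotimes must be finite and non-decreasing")
    bad <- which(!is.finite(microtime) | microtime < 0 | microtime >= laser_period)
    if (length(bad) > 0)
      abort("microtime outside [0, %.4g) ns at record %d (value %.4g)",
            laser_period, bad[1], microtime[bad[1]])
    ch <- as.character(channel)
    badch <- which(!ch %in% c("donor", "acceptor"))
    if (length(badch) > 0)
      abort("unknown channel code '%s' at record %d", ch[badch[1]], badch[1])
    channel <- factor(ch, levels = c("donor", "acceptor"))
  } else {
    channel <- factor(character(0), levels = c("donor", "acceptor"))
  }
  structure(
    list(macrotime = as.numeric(macrotime), microtime = as.numeric(microtime),
         channel = channel, laser_period = laser_period, metadata = metadata),
    class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- length(x$macrotime)
  cat(sprintf("photon_stream: %d photons (%d donor, %d acceptor), period %.4g ns\n",
              n, sum(x$channel == "donor"), sum(x$channel == "acceptor"),
              x$laser_period))
  if (n > 0)
    cat(sprintf("  macrotime range [%.4g, %.4g] s\n",
                x$macrotime[1], x$macrotime[n]))
  invisible(x)
}

#' @export
length.photon_stream <- function(x) length(x$macrotime)

#' Subset a photon stream by record index
#'
#' @param stream A [photon_stream()].
#' @param idx Integer or logical index into the records.
#' @return A `photon_stream` with the selected records.
#' @export
subset_stream <- function(stream, idx) {
  photon_stream(stream$macrotime[idx], stream$microtime[idx],
                stream$channel[idx], stream$laser_period, stream$metadata)
}
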