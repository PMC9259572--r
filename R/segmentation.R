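#' Binned intensity trace
#'
#' Photon counts on a uniform half-open bin grid `[t, t + bin_width)`,
#' one column per channel.
#'
#' @param counts Integer matrix, bins x channels (column names are channel
#'   names), or a vector for a single channel.
#' @param bin_width Bin width, s.
#' @param start_time Time of the first bin edge, s.
#' @return Object of class `intensity_trace`.
#' @export
intensity_trace <- function(counts, bin_width, start_time = 0) {
  check_positive(bin_width, "bin_width")
  if (is.vector(counts))
    counts <- matrix(counts, ncol = 1, dimnames = list(NULL, "intensity"))
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9))
    abort("counts must be non-negative integers")
  structure(list(counts = counts, bin_width = bin_width,
                 start_time = start_time),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace: %d bins x %.4g s, channels: %s\n",
              nrow(x$counts), x$bin_width,
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' Bin a photon stream into an intensity trace
#'
#' Counts photons per channel on the half-open grid `[k*w, (k+1)*w)`. A
#' photon exactly on a bin edge lands in the later bin. With `duration`
#' given, the grid spans `floor(duration / bin_width)` full bins and later
#' photons are dropped; otherwise the grid extends to the bin containing
#' the last photon.
#'
#' @param stream A [photon_stream()].
#' @param bin_width Bin width, s (default 0.1, i.e. 100 ms).
#' @param duration Optional total acquisition time, s.
#' @return An [intensity_trace()] with `donor` and `acceptor` columns.
#' @export
bin_photons <- function(stream, bin_width = 0.1, duration = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  check_positive(bin_width, "bin_width")
  if (length(stream) == 0) abort("cannot bin an empty photon stream")
  n_bins <- if (is.null(duration)) {
    floor(max(stream$macrotime) / bin_width) + 1L
  } else {
    floor(duration / bin_width)
  }
  if (n_bins < 1) abort("duration shorter than one bin")
  idx <- floor(stream$macrotime / bin_width) + 1L
  keep <- idx <= n_bins
  counts <- vapply(c("donor", "acceptor"), function(ch) {
    tabulate(idx[keep & stream$channel == ch], nbins = n_bins)
  }, integer(n_bins))
  intensity_trace(counts, bin_width = bin_width)
}

# Poisson log-likelihood of a constant-rate segment, up to terms that cancel
# in likelihood ratios: s*log(s/m) - s for total s over m bins.
pois_seg_ll <- function(s, m) ifelse(s > 0, s * log(s / m), 0) - s

# Best single split of counts x: returns list(k, lambda, p) where k is the
# last index of the left part, or NULL if no admissible split.
best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  S <- cumsum(x)
  tot <- S[n]
  k <- min_seg:(n - min_seg)
  l1 <- pois_seg_ll(S[k], k)
  l2 <- pois_seg_ll(tot - S[k], n - k)
  l0 <- pois_seg_ll(tot, n)
  lam <- 2 * (l1 + l2 - l0)
  j <- which.max(lam)
  p <- min(1, length(k) * stats::pchisq(lam[j], df = 1, lower.tail = FALSE))
  list(k = k[j], lambda = lam[j], p = p)
}

#' Change-point segmentation of a counting trace
#'
#' Recursive binary segmentation under a Poisson likelihood-ratio test: at
#' each stage the candidate split maximizing the likelihood ratio
#' `2 * (ll_two_rates - ll_one_rate)` is accepted if its chi-squared(1)
#' p-value, Bonferroni-corrected for the number of candidate positions,
#' falls below `alpha`; the two halves are then segmented recursively.
#' Returned segments tile the trace and carry maximum-likelihood rates
#' (counts in segment / bins in segment, exactly).
#'
#' @param trace An [intensity_trace()] (or a bare integer vector).
#' @param alpha Significance level of the per-split test (default 0.01).
#' @param channel Channel column to segment when `trace` has several.
#' @param min_seg Minimum segment length, bins (>= 2).
#' @return Data frame of class `cp_segments` with columns `start_bin`,
#'   `end_bin` (half-open, 1-based), `n_bins`, `total`, `rate` (counts/bin)
#'   and `channel`; attributes `bin_width` and `alpha`.
#' @export
detect_change_points <- function(trace, alpha = 0.01, channel = "donor",
                                 min_seg = 2L) {
  if (inherits(trace, "intensity_trace")) {
    if (!channel %in% colnames(trace$counts))
      abort("trace has no channel '%s'", channel)
    x <- trace$counts[, channel]
    bw <- trace$bin_width
  } else {
    x <- trace
    bw <- NA_real_
  }
  if (any(abs(x - round(x)) > 1e-9)) abort("counts must be integers")
  if (length(x) < 4) abort("trace must have at least 4 bins")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")

  splits <- integer(0)
  recurse <- function(lo, hi) {          # segment is x[lo..hi]
    sp <- best_split(x[lo:hi], min_seg)
    if (is.null(sp) || sp$p >= alpha) return(invisible())
    k <- lo + sp$k - 1L
    splits[[length(splits) + 1L]] <<- k
    recurse(lo, k)
    recurse(k + 1L, hi)
  }
  recurse(1L, length(x))

  b <- c(0L, sort(splits), length(x))
  seg <- data.frame(start_bin = b[-length(b)] + 1L, end_bin = b[-1] + 1L)
  seg$n_bins <- seg$end_bin - seg$start_bin
  seg$total <- vapply(seq_len(nrow(seg)), function(i)
    sum(x[seg$start_bin[i]:(seg$end_bin[i] - 1L)]), numeric(1))
  seg$rate <- seg$total / seg$n_bins
  seg$channel <- channel
  attr(seg, "bin_width") <- bw
  attr(seg, "alpha") <- alpha
  class(seg) <- c("cp_segments", "data.frame")
  seg
}

#' Classify photobleaching steps among segment boundaries
#'
#' A bleach step is a downward segment boundary whose following segment's
#' rate lies within 3 Poisson standard errors of the background rate,
#' i.e. `|rate_after - bg| <= 3 * sqrt(bg / n_bins_after)` (for `bg = 0`
#' the following segment must be empty).
#'
#' @param segments Output of [detect_change_points()].
#' @param background_rate Expected background, counts/bin (>= 0).
#' @return List with `n_steps` and a data frame `steps` (boundary bin,
#'   time in s when the bin width is known, rates before/after).
#' @export
classify_bleach_steps <- function(segments, background_rate) {
  stopifnot(inherits(segments, "cp_segments"))
  if (background_rate < 0) abort("background_rate must be >= 0")
  bw <- attr(segments, "bin_width")
  n <- nrow(segments)
  steps <- data.frame(boundary_bin = integer(0), time_s = numeric(0),
                      from_rate = numeric(0), to_rate = numeric(0))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      after <- segments[i + 1, ]
      tol <- 3 * sqrt(background_rate / after$n_bins)
      at_bg <- if (background_rate == 0) after$total == 0
               else abs(after$rate - background_rate) <= tol
      if (segments$rate[i] > after$rate && at_bg) {
        steps <- rbind(steps, data.frame(
          boundary_bin = segments$end_bin[i] - 1L,
          time_s = if (is.na(bw)) NA_real_ else (segments$end_bin[i] - 1L) * bw,
          from_rate = segments$rate[i], to_rate = after$rate))
      }
    }
  }
  list(n_steps = nrow(steps), steps = steps)
}

#' Accept or reject a trace as a single donor/acceptor pair
#'
#' Segments both channels, classifies bleach steps against the supplied
#' background, and accepts the molecule only if each channel shows exactly
#' one photobleaching step with the acceptor step preceding the donor step.
#'
#' @param trace A two-channel [intensity_trace()] from [bin_photons()].
#' @param background Named vector `c(donor=, acceptor=)` of background
#'   rates in counts/bin (a scalar is recycled).
#' @param alpha Change-point significance (see [detect_change_points()]).
#' @param min_photons Minimum total photons for the molecule to be usable.
#' @return List of class `trace_decision`: `accepted`, `reason` (one of
#'   `ok`, `too_few_photons`, `no_acceptor_bleach`,
#'   `multiple_acceptor_steps`, `no_donor_bleach`, `multiple_donor_steps`),
#'   `acceptor_bleach_time`, `donor_bleach_time`, and the per-channel
#'   segment tables.
#' @export
select_single_pair_trace <- function(trace, background, alpha = 0.01,
                                     min_photons = 1000) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (!all(c("donor", "acceptor") %in% colnames(trace$counts)))
    abort("trace must have donor and acceptor channels on a shared bin grid")
  if (length(background) == 1) background <- c(donor = unname(background),
                                               acceptor = unname(background))
  decision <- function(accepted, reason, ab = NA_real_, db = NA_real_,
                       segs = NULL) {
    structure(list(accepted = accepted, reason = reason,
                   acceptor_bleach_time = ab, donor_bleach_time = db,
                   segments = segs),
              class = "trace_decision")
  }
  if (sum(trace$counts) < min_photons)
    return(decision(FALSE, "too_few_photons"))

  seg_d <- detect_change_points(trace, alpha, channel = "donor")
  seg_a <- detect_change_points(trace, alpha, channel = "acceptor")
  st_d <- classify_bleach_steps(seg_d, background[["donor"]])
  st_a <- classify_bleach_steps(seg_a, background[["acceptor"]])
  segs <- list(donor = seg_d, acceptor = seg_a)

  if (st_a$n_steps == 0) return(decision(FALSE, "no_acceptor_bleach", segs = segs))
  if (st_a$n_steps > 1) return(decision(FALSE, "multiple_acceptor_steps", segs = segs))
  if (st_d$n_steps == 0) return(decision(FALSE, "no_donor_bleach", segs = segs))
  if (st_d$n_steps > 1) return(decision(FALSE, "multiple_donor_steps", segs = segs))
  ab <- st_a$steps$time_s[1]
  db <- st_d$steps$time_s[1]
  if (ab >= db) return(decision(FALSE, "no_acceptor_bleach", segs = segs))
  decision(TRUE, "ok", ab = ab, db = db, segs = segs)
}

#' @export
print.trace_decision <- function(x, ...) {
  cat(sprintf("trace_decision: %s (%s)\n",
              if (x$accepted) "accepted" else "rejected", x$reason))
  if (x$accepted)
    cat(sprintf("  acceptor bleach %.2f s, donor bleach %.2f s\n",
                x$acceptor_bleach_time, x$donor_bleach_time))
  invisible(x)
}

#' Extract per-level donor photons from an accepted trace
#'
#' Donor photons arriving before the acceptor bleach are FRET-level photons;
#' they are partitioned by the donor-channel segment boundaries overlapping
#' that interval. Donor photons between the acceptor and donor bleaches are
#' returned separately as donor-only reference photons.
#'
#' @param stream The molecule's [photon_stream()].
#' @param segments Donor-channel segments from [detect_change_points()].
#' @param acceptor_bleach_time Acceptor bleach time, s.
#' @param donor_bleach_time Optional donor bleach time, s; donor-only
#'   photons are clipped there (photons after it are background).
#' @return List with `levels` (list of per-level lists: `macrotime`,
#'   `microtime`, `start`, `end`) and `donor_only` (same layout).
#' @export
extract_fret_levels <- function(stream, segments, acceptor_bleach_time,
                                donor_bleach_time = NULL) {
  stopifnot(inherits(stream, "photon_stream"), inherits(segments, "cp_segments"))
  bw <- attr(segments, "bin_width")
  if (is.na(bw)) abort("segments lack a bin width; segment an intensity_trace")
  t_max <- max(stream$macrotime)
  if (acceptor_bleach_time <= 0 || acceptor_bleach_time > t_max)
    abort("acceptor_bleach_time %.4g s lies outside the trace (max %.4g s)",
          acceptor_bleach_time, t_max)
  don <- stream$channel == "donor"
  # level boundaries: donor segment edges strictly inside (0, bleach)
  edges <- (segments$end_bin - 1L) * bw
  inner <- edges[edges > 0 & edges < acceptor_bleach_time]
  bounds <- c(0, inner, acceptor_bleach_time)
  lev_idx <- findInterval(stream$macrotime, bounds, rightmost.closed = FALSE)
  levels <- lapply(seq_len(length(bounds) - 1L), function(i) {
    sel <- don & lev_idx == i & stream$macrotime < acceptor_bleach_time
    list(macrotime = stream$macrotime[sel], microtime = stream$microtime[sel],
         start = bounds[i], end = bounds[i + 1])
  })
  end_ref <- donor_bleach_time %||% (t_max + 1e-9)
  sel <- don & stream$macrotime >= acceptor_bleach_time &
    stream$macrotime < end_ref
  donor_only <- list(macrotime = stream$macrotime[sel],
                     microtime = stream$microtime[sel],
                     start = acceptor_bleach_time, end = end_ref)
  list(levels = levels, donor_only = donor_only)
}
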