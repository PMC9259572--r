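# shared fixture builders; everything is generated in code at test time

# two-channel intensity trace from explicit per-bin counts
make_trace <- function(donor, acceptor = NULL, bin_width = 0.1) {
  acceptor <- acceptor %||% rep(0L, length(donor))
  smfretr::intensity_trace(
    cbind(donor = as.integer(donor), acceptor = as.integer(acceptor)),
    bin_width = bin_width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a short two-level smFRET config used by several tests
two_level_config <- function(seed, tau = c(3.0, 1.5), dur = c(3, 5),
                             donor_bleach = 12, ...) {
  smfretr::smfret_sim_config(
    true_lifetimes = data.frame(duration = dur, tau = tau),
    donor_bleach_time = donor_bleach, seed = seed, ...)
}

# cheap FCS config for unit-scale Brownian runs (large beam waist so the
# time step can stay coarse)
cheap_fcs_config <- function(seed, D = 1e-7, duration = 20) {
  smfretr::fcs_sim_config(
    diffusion_coefficient = D, beam_waist = 0.5, aspect_ratio = 0.2,
    mean_occupancy = 2, brightness = 3e4, background_rate = 0,
    duration = duration, time_step = 2e-4, box_size = 5, seed = seed)
}

# unique scratch path under the session tempdir
withr_local_file <- function(name) {
  tempfile(pattern = sub("\\..*$", "_", name),
           fileext = sub("^[^.]*", "", name))
}

# independent rebin-by-2 used to cross-check the multi-tau octaves
rebin2 <- function(x) {
  n2 <- length(x) %/% 2L
  x <- x[seq_len(2L * n2)]
  x[seq(1, 2 * n2, by = 2)] + x[seq(2, 2 * n2, by = 2)]
}
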