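---
title: "Methods: photon-stream smFRET lifetime analysis and FCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon-stream smFRET lifetime analysis and FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfretr)
```

This vignette is the package's own account of the statistical models it
implements, the choices that were genuinely open, and what the synthetic
data generator does and does not emulate.

## The measurement model

An immobilized receptor carries one donor dye; one acceptor dye sits in
the surrounding membrane. Pulsed excitation at 80 MHz (laser period
12.5 ns) and time-correlated single-photon counting record, for every
photon, its absolute arrival time (*macrotime*, seconds), its delay after
the excitation pulse (*microtime*, nanoseconds) and the detection channel.
FRET opens a non-radiative decay channel, so the donor lifetime shortens
with proximity: the donor-acceptor distance follows from
$E = 1 - \tau_{DA}/\tau_D$ and $r = r_0\,((1-E)/E)^{1/6}$, with the
dye-pair calibration $r_0 = 8.49$ nm and donor-only reference
$\tau_D = 3.32$ ns held fixed throughout (`fret_calibration()`). We never
recompute $r_0$ from dye spectra or orientation factors; it enters as a
constant.

## Intensity segmentation

Photon streams are binned at 100 ms (`bin_photons()`, half-open bins,
edge photons land in the later bin). Regions of constant emission are
found by recursive binary segmentation under a Poisson likelihood-ratio
test (`detect_change_points()`): for a candidate split of a segment into
counts with rates $\lambda_1, \lambda_2$ versus a single rate $\lambda$,
$\Lambda = 2[\ell_1 + \ell_2 - \ell_0]$ is referred to $\chi^2_1$, with a
Bonferroni correction over the candidate split positions, at a default
significance `alpha = 0.01`. The literature names change-point analysis
for this step but no specific algorithm or threshold; binned Poisson
binary segmentation was chosen because it is standard for counting traces,
exactly testable, and idempotent (re-segmenting a returned segment finds
nothing new, which the test suite checks). Segment rates are exactly
(photons in segment)/(bins in segment). Photon-by-photon (unbinned)
change-point detection and HMM dwell analysis are out of scope.

A *photobleaching step* is a downward segment boundary whose following
rate lies within 3 Poisson standard errors of the background rate
(`classify_bleach_steps()`). "Single-molecule" acceptance then requires
exactly one such step per channel with the acceptor step first
(`select_single_pair_trace()`); every rejection carries a reason code, and
the per-molecule decisions table is part of the pipeline output. The
spec's reason enumeration was extended with `no_donor_bleach` for donor
channels that never bleach: labelling that case "multiple steps" would
mislead an auditor. Background rates are taken from configuration (the
instrument measures background separately); when a trace is accepted, the
post-donor-bleach tail is available as an internal check.

## Bunch-wise lifetime estimation

Donor photons before the acceptor bleach, split at donor segment
boundaries, form FRET levels; each level is cut into consecutive bunches
of exactly 1000 photons (trailing remainder discarded). Each bunch's
microtimes are histogrammed on the IRF's native grid (default 256 bins
over 12.5 ns, about 49 ps/bin) and fitted by maximizing the multinomial
log-likelihood under

$$p_k(\tau) = (1 - f_{bg})\,[\mathrm{IRF} \circledast e^{-t/\tau}]_k
            + f_{bg}\, b_k,$$

where $\circledast$ is *circular* convolution over the laser period and
$b_k$ is the measured background histogram (uniform if none is supplied).
Numerical choices:

* **Circular convolution.** At 80 MHz a 3.3-ns lifetime leaves ~2% of the
  decay in the next excitation cycle; wrapping the exponential on the
  period makes the model exact for periodic excitation. Because the
  wrapped exponential is proportional to $e^{-t/\tau}$ on one period, FFT
  convolution of the single-period kernel is exact after normalization.
* **Fixed background fraction.** $f_{bg}$ is set from the measured
  background rate times the bunch's time span, not fitted — fitting it
  per 1000-photon bunch would mostly absorb decay tail and inflate
  variance.
* **Bounded 1-D optimization.** $\tau$ is searched on
  (0.05, period − 0.05) ns by `stats::optimize()`; the 68% half-width
  comes from the observed information (central-difference curvature of
  the negative log-likelihood, step $10^{-3}$ ns).
* **Flags, not silences.** An optimum within 0.1 ns of a search bound, or
  a curvature too flat to define a standard error, flags the estimate;
  flagged estimates are excluded from distributions by default but stay
  in the bunch table. Bunches fitted at or above $\tau_D$ (so $E \le 0$)
  keep `r = NA` with `valid = FALSE` — they are physically donor-only and
  must remain auditable, so they are never clipped into the valid range.

Calibration at the study conditions (200 bunches of 1000 photons,
$\tau = 2.5$ ns, Gaussian IRF $\sigma = 0.15$ ns, 5% background) puts the
mean bias under 2% and the empirical scatter within 30% of the
information-based standard error; both are asserted in the test suite.
The residual ~1% positive bias comes from histogram quantization and the
fixed-background approximation and is far below the ~3% per-bunch
statistical error.

Per-bunch lifetimes are histogrammed with the square-root rule: the *bin
count* is `round(sqrt(n_bunches))`. "Bin sizes from the square root of
the number of bunches" can be read as a bin count or a bin width; bin
count is adopted, isolated
in `build_lifetime_distribution()` so the alternative is a one-line
change. Medians and quartiles are computed on raw values, never on the
histogram. Conditions are compared by one-way ANOVA (`stats::aov`) with
the significance flag at $P \le 0.001$; identical groups give $F = 0$ and
zero within-group variance gives an explicit undefined result.

## FCS

Intensity traces of diffusing nanodiscs are autocorrelated with a
multi-tau scheme (`autocorrelate_multitau()`, default `m = 16` lags per
octave, counts rebinned by 2 per octave) using symmetric normalization
$G(k) = \langle a b\rangle / (\langle a\rangle\langle b\rangle)$ over the
overlapping subtraces, which removes the leading finite-trace bias. The
correlator is checked against a deliberately naive $O(n\,k)$ direct
implementation to $10^{-10}$ on every octave. Curves are fitted to the
one-species 3D diffusion model

$$G(\tau) = 1 + \frac{1}{N}\,\frac{1}{(1+\tau/\tau_d)\sqrt{1+s^2\tau/\tau_d}}$$

by Levenberg-Marquardt (`minpack.lm::nlsLM`). The aspect ratio $s$ and
$N$ are weakly identifiable on noisy curves, so the pipeline fixes $s$ at
the instrument calibration value by default (fitting it is one argument
away). `fit_fcs_model()` weights lags uniformly by default; the pipeline
passes $1/\tau$ weights because the correlator variance grows roughly
linearly with lag (fewer independent samples), and with uniform weights
the dense, uninformative long-lag baseline dominates the residuals.

Diffusion times convert to coefficients via $D = \omega^2/(4\tau_d)$ and
to hydrodynamic radii via Stokes-Einstein $R = k_B T/(6\pi\eta D)$.
Defaults: beam waist $\omega = 0.3\ \mu$m (typical for ~550-nm confocal
excitation at NA 1.4; the waist is an instrument property, not a
published number), $T = 294.15$ K and $\eta = 0.978$ mPa·s (water at the
stated room temperature, 21 °C). The percent radius change between
conditions, $100(1 - D_{without}/D_{with})$, cancels $T$, $\eta$ and
$\omega$ entirely, which is why the compaction is the robust observable.
Salt dependence is fitted by $\Delta R(c) = a\,e^{-b\sqrt{c}}$
(`fit_salt_screening()`); with exactly two points the fit reproduces the
closed-form interpolation, and a fixed-$b$ variant solves the amplitude
in closed form.

## What the synthetic data emulate — and what they do not

`simulate_smfret_experiment()` generates, per molecule: piecewise-constant
Poisson photon arrivals (FRET levels with configured durations and
lifetimes, then a donor-only stretch, then background-only after donor
bleach); donor microtimes composed as IRF sample + exponential delay,
wrapped on the laser period; uniform-microtime background in both
channels. The donor rate during a level scales as
$\tau_{DA}/\tau_D$ — the quantum-yield scaling that makes level
boundaries and the acceptor bleach visible as intensity steps, as in real
traces. Bleach times are fixed configuration inputs so a seed fully
determines the stream (`smfret_sim_config_random_bleach()` samples them
exponentially when realism matters more than determinism). Seeds are
mandatory; identical seeds give bit-identical streams.

`simulate_fcs_intensity()` performs Brownian dynamics of point emitters
(Gaussian steps of $\sqrt{2D\,dt}$ per axis) in a periodic box through a
3D Gaussian detection profile, with Poisson counts per time step. The
box is 12 beam waists wide transversally and at least 3 axial waists
along the optical axis; the time-step invariant
$\sqrt{4D\,dt} < \omega/5$ keeps single steps well inside the focus. The
simulator emits binned counts rather than photons because the multi-tau
correlator consumes counts and photon-level detail adds nothing to the
diffusion model. Known residual artifact: with a finite periodic box and
a fixed emitter count, the realized correlation decays a few percent
faster than the ideal infinite-reservoir model, so recovered diffusion
coefficients carry a systematic error of roughly +4% — inside every
tolerance used here, and stated rather than hidden.

Deliberately **not** emulated (so passing tests say nothing about these):
triplet blinking and other dye photophysics beyond a mono-exponential
donor decay, spectral crosstalk, acceptor direct excitation, dye
rotational dynamics (the 100-ms observation window averages over them),
multi-species or anomalous diffusion, and detector afterpulsing/dead
time. Real data failing these assumptions will not be flagged by this
pipeline's tests.

## Default scales and run times

The generator defaults emulate plausible single-molecule conditions:
5 kHz unquenched donor rate, 5 kHz acceptor rate, 0.2 kHz background per
channel, 10-60 s traces — count rates and trace durations are instrument-
and sample-dependent, so these are configurable, realistic-scale choices. Pipeline analyses in the test suite use 4-6 molecules per
condition with 15-s FRET levels (several hundred 1000-photon bunches per
condition), and FCS runs use 60-s traces at a 50-µs time step (~34,000
focal transits at $\tau_d \approx 1.8$ ms), chosen so that every
statistical bound being asserted has comfortable headroom at desk scale.

## Known limitations

* Distances inherit the calibration constants; nanometre-level output
  precision does not imply nanometre accuracy if $r_0$ or $\tau_D$ are
  off.
* The lifetime model is strictly mono-exponential per bunch; bi-modal
  *distributions* across bunches are resolved, bi-exponential decay
  *within* a bunch is not.
* The change-point stage assumes Poisson counting statistics; detector
  artifacts that overdisperse the counts would inflate the false-split
  rate.
* FCS amplitude ($N$) estimates absorb uncorrelated background; only
  $\tau_d$-derived quantities are treated as calibrated observables.
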