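# smfretr

Photon-stream analysis for single-molecule FRET lifetimes and fluorescence
correlation spectroscopy (FCS), built around the measurement scheme used to
detect ligand-induced intracellular conformational changes in monomeric,
nanodisc-embedded membrane receptors such as EGFR.

## The problem and who this is for

A single receptor carries one donor dye on its intracellular C-terminus and
one acceptor dye in the membrane. Energy transfer between them competes
with donor emission, so the donor fluorescence lifetime shortens as the
C-terminus approaches the membrane. A TCSPC confocal microscope records
every detected photon as a (macrotime, microtime, channel) triple; turning
those streams into distance distributions, and diffusing-particle intensity
traces into hydrodynamic radii, requires a chain of statistical steps that
this package implements as tested, reusable functions:

1. **Binning & segmentation** — 100-ms intensity traces; recursive binary
   change-point segmentation under a Poisson likelihood-ratio test
   (Bonferroni-corrected, default alpha 0.01).
2. **Trace selection** — molecules are kept only when the donor and the
   acceptor each show exactly one photobleaching step, acceptor first.
3. **FRET levels & bunches** — donor photons before acceptor bleaching,
   split at segment boundaries, grouped into consecutive bunches of 1000.
4. **Lifetime fitting** — per bunch, maximum-likelihood fit of a
   mono-exponential decay circularly convolved with the instrument
   response function (IRF) over the 12.5-ns laser period (80 MHz), plus a
   separately measured background term:
   `p_k(tau) = (1 - f_bg) [IRF * exp(-t/tau)]_k + f_bg bg_k`.
5. **Distances** — `E = 1 - tau_DA / tau_D` and
   `r = r0 ((1 - E)/E)^(1/6)` with `tau_D = 3.32` ns, `r0 = 8.49` nm.
6. **FCS** — multi-tau autocorrelation,
   `G(tau) = 1 + (1/N) / ((1 + tau/tau_d) sqrt(1 + s^2 tau/tau_d))`,
   `D = omega^2 / (4 tau_d)`, Stokes-Einstein `R = k_B T / (6 pi eta D)`,
   and the Debye-Hueckel screening fit `dR(c) = a exp(-b sqrt(c))`.

A synthetic-data module (`simulate_smfret_experiment()`,
`simulate_fcs_intensity()`, `generate_salt_series()`) generates photon
streams and Brownian-dynamics intensity traces with full ground-truth
bookkeeping, so every stage of the chain is testable without experimental
data.

## Worked example

Simulate two ligand conditions (ground-truth donor lifetimes 3.0 ns and
1.5 ns, six molecules each), run the full pipeline, and convert the
medians to distances:

```r
library(smfretr)

conditions <- list(
  list(label = "no_EGF", n_molecules = 6,
       sim = smfret_sim_config(
         true_lifetimes = data.frame(duration = 15, tau = 3.0),
         donor_bleach_time = 18, seed = 1)),
  list(label = "EGF", n_molecules = 6,
       sim = smfret_sim_config(
         true_lifetimes = data.frame(duration = 15, tau = 1.5),
         donor_bleach_time = 18, seed = 1)))

run <- run_smfret_pipeline(conditions, seed = 20260923)
run
#> smfret_run: 12 molecules in, 12 accepted, 638 bunches (0 flagged)
#>   no_EGF: median tau 3.033 ns (n = 420)
#>   EGF: median tau 1.534 ns (n = 218)
#>   ANOVA: F = 2.57e+04 on (1, 636) df, P = 0

distance_from_lifetime(c(3.0, 1.5))
#>   tau_da          E      r_nm r_nm_rounded valid
#> 1    3.0 0.09638554 12.328292           12  TRUE
#> 2    1.5 0.54819277  8.220742            8  TRUE
```

The recovered medians sit within ~2% of the simulated truth, the two
conditions are separated far beyond the P <= 0.001 flag, and the median
lifetimes map to 12 nm (unliganded) versus 8 nm (ligand-bound) — the 2x
lifetime contrast reads out as a ~4 nm approach of the receptor tail to
the membrane.

The numbered scripts under `analysis/` run the full set of analyses
(`01` smFRET lifetimes, `02` distance table for all ligand/bilayer
conditions, `03` FCS diffusion and radius compaction, `04` Debye-Hueckel
salt screening) and write their tables under `results/`:

```sh
Rscript analysis/01_smfret_lifetimes.R
Rscript analysis/03_fcs_diffusion.R   # ~2 minutes: two 60 s Brownian runs
```

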