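#!/usr/bin/env Rscript
# Single-molecule FRET lifetime analysis at the neutral-bilayer study
# conditions: simulate immobilized EGFR nanodiscs with and without ligand
# (ground-truth donor lifetimes 3.0 ns and 1.5 ns), run the full photon
# pipeline, and compare the recovered lifetime distributions.

suppressPackageStartupMessages(library(smfretr))

out_dir <- "results/smfret_neutral"
seed <- 20260923

conditions <- list(
  list(label = "no_EGF", n_molecules = 6,
       sim = smfret_sim_config(
         true_lifetimes = data.frame(duration = 15, tau = 3.0),
         donor_bleach_time = 18, seed = 1)),
  list(label = "EGF", n_molecules = 6,
       sim = smfret_sim_config(
         true_lifetimes = data.frame(duration = 15, tau = 1.5),
         donor_bleach_time = 18, seed = 1)))

run <- run_smfret_pipeline(conditions, seed = seed, out_dir = out_dir)
print(run)

cat("\nRecovered vs true medians:\n")
for (truth in list(c("no_EGF", 3.0), c("EGF", 1.5))) {
  d <- run$distributions[[truth[1]]]
  cat(sprintf("  %-7s median %.3f ns (truth %s ns, %+.1f%%), %d bunches in %d bins\n",
              truth[1], d$median, truth[2],
              100 * (d$median / as.numeric(truth[2]) - 1), d$n, d$n_bins))
}
cat(sprintf("\nOne-way ANOVA between conditions: F = %.4g on (%d, %d) df, P = %.3g (flag at P <= 0.001: %s)\n",
            run$anova$F, run$anova$df1, run$anova$df2, run$anova$p,
            run$anova$significant))
cat(sprintf("Tables written under %s\n", out_dir))
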