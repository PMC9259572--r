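#!/usr/bin/env Rscript
# FCS diffusion analysis: Brownian-dynamics simulations of nanodisc
# diffusion at the two measured diffusion coefficients (with / without
# ligand), multi-tau autocorrelation, one-species diffusion-model fits,
# and the Stokes-Einstein hydrodynamic radii with the percent compaction.

suppressPackageStartupMessages(library(smfretr))

out_dir <- "results/fcs_diffusion"
seed <- 20260923

conditions <- list(
  list(label = "with_EGF",
       sim = fcs_sim_config(diffusion_coefficient = 1.27e-7, seed = 1)),
  list(label = "without_EGF",
       sim = fcs_sim_config(diffusion_coefficient = 0.98e-7, seed = 1)))

cat("Simulating two 60 s FCS acquisitions (this takes a couple of minutes)...\n")
run <- run_fcs_pipeline(conditions, seed = seed,
                        compare = c("with_EGF", "without_EGF"),
                        out_dir = out_dir)
print(run)

cat("\nRecovery against ground truth:\n")
for (i in seq_len(nrow(run$fits))) {
  f <- run$fits[i, ]
  cat(sprintf("  %-12s D = %.3g cm^2/s (truth %.3g, %+.1f%%), tau_d = %.2f ms, R = %.1f nm\n",
              f$condition, f$D_cm2_s, f$true_D,
              100 * (f$D_cm2_s / f$true_D - 1), 1e3 * f$tau_d, f$R_nm))
}
truth_dr <- percent_radius_change(1.27e-7, 0.98e-7)
cat(sprintf("\nRadius change on ligand binding: %.1f%% recovered vs %.1f%% from the input coefficients\n",
            run$delta_r_pct, truth_dr))
cat(sprintf("(the input pair itself gives a %d%% compaction, integer-truncated)\n",
            trunc(truth_dr)))
cat(sprintf("Tables written under %s\n", out_dir))
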