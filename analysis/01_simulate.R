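#!/usr/bin/env Rscript
# Stage 1: synthesise the study-shaped strain trajectories.
#
# No raw strain data is deposited for this experiment, so the whole workflow
# runs on synthetic trajectories that carry the measured structure: averaged
# pre-fatigue strains 2819/2807 microstrain, a two-phase compressive rise
# with a kink at 28% of life, a 4% total tensile rise, and (for the noisy
# replicate) 20 microstrain additive measurement noise.

suppressPackageStartupMessages(library(bimodbeam))
seed <- 1L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

noiseless <- generate_trajectory(trajectory_generator_params(noise_sd = 0),
                                 specimen_id = "synthetic_noiseless")
noisy <- generate_trajectory(trajectory_generator_params(noise_sd = 20,
                                                         seed = seed),
                             specimen_id = "synthetic_noisy")
write_trajectory_csv(noiseless, file.path(out, "trajectory_noiseless.csv"))
write_trajectory_csv(noisy, file.path(out, "trajectory_noisy.csv"))

cat("Synthetic trajectories written to", out, "\n")
cat(sprintf("  noiseless: eps_C %g -> %g ue (kink at t = 0.28), eps_T %g -> %g ue (+%.1f%%)\n",
            noiseless$eps_C_ue[1], noiseless$eps_C_ue[11],
            noiseless$eps_T_ue[1], noiseless$eps_T_ue[11],
            100 * (noiseless$eps_T_ue[11] / noiseless$eps_T_ue[1] - 1)))
cat(sprintf("  noisy (seed %d): same means + 20 ue Gaussian noise\n", seed))
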