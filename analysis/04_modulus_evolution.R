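#!/usr/bin/env Rscript
# Stage 4: the modulus surface E(y, t).
#
# With the gradient parameters solved at every life fraction, the modulus
# profile across the section is tabulated in long format (height measured
# from the instantaneous neutral axis). The compression side softens
# progressively away from the axis while the neutral-axis modulus stays
# anchored at E0.

suppressPackageStartupMessages(library(bimodbeam))
out <- "results/analysis"
traj <- read_trajectory_csv(file.path(out, "trajectory_noiseless.csv"))
geom <- specimen_geometry()
sigma_meas <- loading_protocol()$measurement_stress
E0 <- calibrate_E0(traj$eps_C_ue[1], traj$eps_T_ue[1], sigma_meas)
res <- analyze_trajectory(traj, geom, E0,
                          bending_moment_from_stress(sigma_meas, geom))

tab <- modulus_evolution_report(res, n_y = 25)
write_table_csv(tab, file.path(out, "modulus_evolution.csv"))

last <- tab[tab$t == 1, ]
cat(sprintf("modulus surface written (%d rows)\n", nrow(tab)))
cat(sprintf("end of life: E at compressed surface %.0f MPa, at tensile surface %.0f MPa, E0 %.0f MPa\n",
            last$E_MPa[which.max(last$y_mm)], last$E_MPa[which.min(last$y_mm)],
            E0))
cat(sprintf("compressed-surface modulus dropped %.1f%% from t = 0 to t = 1\n",
            100 * (1 - last$E_MPa[which.max(last$y_mm)] /
                     tab$E_MPa[tab$t == 0][which.max(tab$y_mm[tab$t == 0])])))
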