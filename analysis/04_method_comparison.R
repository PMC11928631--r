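#!/usr/bin/env Rscript
# 04 — method comparison.
#
# Compares two assays of the same twelve samples: the crude-lysate plate
# from step 01 and an independently simulated "standard" assay of the
# identical true concentrations (its own droplet draws and noise, a
# different seed). Reports linearity (OLS slope/intercept/r2, slope CI vs
# 1), Spearman rank agreement, and Bland-Altman bias with limits of
# agreement, in targets/cell. Writes results/comparison_pairs.csv and
# results/comparison_summary.csv.

suppressPackageStartupMessages(library(dropletquant))

tpc_by_group <- function(plate) {
  res <- run_pipeline(plate, run_config())
  q <- res$quantification
  t <- q[q$channel == "target", c("group", "targets_per_cell")]
  setNames(t$targets_per_cell, t$group)
}

crude_plate <- read_plate("results/plate")
crude <- tpc_by_group(crude_plate)

# the standard assay: same samples, independent measurement
base2 <- sim_config(seed = 774411L)
std_plate <- simulate_dilution_series(
  base2, targets_per_cell = c(0.016, 0.0016, 0.0006, 0.0003),
  cells_per_well = 2500, replicates = 3, wells_per_group = 4)
std_plate <- simulate_blank_panel(base2, n_ntc = 4, n_clc = 4,
                                  plate = std_plate)
standard <- tpc_by_group(std_plate)

common <- intersect(names(crude), names(standard))
x <- standard[common]  # reference method
y <- crude[common]     # test method

fit <- linear_fit(x, y, labels = common)
rho <- spearman_rho(x, y)
ba <- bland_altman(x, y, labels = common)

message(sprintf("OLS: y = %.4f x + %.6f, r2 = %.4f", fit$slope,
                fit$intercept, fit$r2))
message(sprintf("slope 95%% CI [%.4f, %.4f] (contains 1: %s)",
                fit$slope_ci95[1], fit$slope_ci95[2],
                fit$slope_ci_contains_one))
message(sprintf("Spearman rho = %.4f", rho))
message(sprintf(
  "Bland-Altman (%s): bias %.6f, SD %.6f, LoA [%.6f, %.6f]",
  ba$direction, ba$bias, ba$sd_diff, ba$loa[1], ba$loa[2]))

write.csv(data.frame(sample = common, standard = x, crude = y),
          "results/comparison_pairs.csv", row.names = FALSE)
write.csv(data.frame(
  slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
  slope_ci_low = fit$slope_ci95[1], slope_ci_high = fit$slope_ci95[2],
  slope_ci_contains_one = fit$slope_ci_contains_one,
  spearman_rho = rho, ba_bias = ba$bias, ba_sd = ba$sd_diff,
  ba_loa_low = ba$loa[1], ba_loa_high = ba$loa[2]),
  "results/comparison_summary.csv", row.names = FALSE)
message("comparison outputs in results/")
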