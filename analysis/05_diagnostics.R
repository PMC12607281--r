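#!/usr/bin/env Rscript
# Step 5 — goodness-of-fit diagnostics for the fitted model.
#
# Visual predictive check (500 simulated study replicates, one bin per
# nominal sampling time, stratified by administration and analyte) and
# population/individual weighted residuals. Numbers go to CSV; the VPC
# figure is a convenience by-product.

library(cbgpk)

ds <- read_pk_dataset("results/study_dataset.csv")
fit <- readRDS("results/fit.rds")

v <- vpc(ds, fit$pop, n_sim = 500, seed = 11)
write.csv(as.data.frame(v), "results/vpc.csv", row.names = FALSE)
df <- as.data.frame(v)
in_band <- mean(df$obs_p50 >= df$sim_p50_lo & df$obs_p50 <= df$sim_p50_hi)
message(sprintf("VPC: observed medians inside the simulated median band in %.0f%% of %d bins.",
                100 * in_band, nrow(df)))
ggplot2::ggsave("results/vpc.png", vpc_plot(v), width = 10, height = 7,
                dpi = 150)

rt <- residual_table(ds, fit, n_sim = 300, seed = 12)
write.csv(as.data.frame(rt), "results/residuals.csv", row.names = FALSE)
message(sprintf("Residuals: %.1f%% of IWRES and %.1f%% of PWRES beyond |2| (reference ~5%%).",
                100 * attr(rt, "frac_iwres_gt2"),
                100 * attr(rt, "frac_pwres_gt2")))
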