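#!/usr/bin/env Rscript
# Time-resolved decays across a crowder series: biexponential reconvolution
# fits with bootstrap confidence intervals, and the amplitude-weighted
# lifetime trend that mirrors progressive donor quenching by FRET.

library(luvfret)

out_dir <- file.path("results", "02_lifetime_series")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 202

# DiI decays: fixed fast component, slow component quenched as crowding
# increases; 80 MHz excitation (12.5 ns window), 1e4 peak counts
conditions <- data.frame(label = c("0M", "1M", "2M", "3M"),
                         tau2_ns = c(2.4, 2.1, 1.8, 1.5))
rows <- list()
for (i in seq_len(nrow(conditions))) {
  comp <- data.frame(amplitude = c(0.6, 0.4),
                     lifetime_ns = c(0.5, conditions$tau2_ns[i]))
  g <- simulate_decay(components = comp, seed = seed + i)
  bs <- bootstrap_lifetimes(g$decay, g$irf, n_components = 2, n_boot = 100,
                            seed = seed + 100 + i)
  rows[[i]] <- data.frame(
    label = conditions$label[i],
    tau1_ns = bs$fit$components$lifetime_ns[1],
    tau2_ns = bs$fit$components$lifetime_ns[2],
    tau_av_ns = bs$fit$tau_av_ns,
    tau_av_lo = bs$intervals["2.5%", "tau_av"],
    tau_av_hi = bs$intervals["97.5%", "tau_av"],
    tau_av_true = amplitude_weighted_lifetime(comp),
    chi2_reduced = bs$fit$chi2_reduced)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "lifetime_series.csv"), row.names = FALSE)

cat("\nAmplitude-weighted lifetime across the series:\n")
print(tab, digits = 4)
cat(sprintf("\ntau_av decreases monotonically: %s\n",
            all(diff(tab$tau_av_ns) < 0)))
cat(sprintf("truth inside every 95%% bootstrap interval: %s\n",
            all(tab$tau_av_true >= tab$tau_av_lo &
                  tab$tau_av_true <= tab$tau_av_hi)))
cat("Table written under", out_dir, "\n")
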