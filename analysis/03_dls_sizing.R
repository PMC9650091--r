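#!/usr/bin/env Rscript
# Vesicle sizing: single-exponential inversion of backscatter correlograms
# via Stokes-Einstein across the 100-1000 nm range, plus log-normal
# summary statistics for an electron-microscopy style diameter table.

library(luvfret)

out_dir <- file.path("results", "03_dls_sizing")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 303

st <- dls_recovery_study(d_H_nm = c(100, 227, 400, 1000), n_seeds = 20,
                         noise_sd = 0.01, base_seed = seed)
write.csv(st$runs, file.path(out_dir, "dls_recovery_runs.csv"),
          row.names = FALSE)
write.csv(st$summary, file.path(out_dir, "dls_recovery_summary.csv"),
          row.names = FALSE)
cat("\nMedian |d_H| recovery error at 1% correlogram noise:\n")
print(st$summary, digits = 3)

# log-normal size table like an EM histogram: mode 132 nm, FWHM 125 nm,
# summarized with 25-nm bins
g <- simulate_diameters(2000, mode_nm = 132, fwhm_nm = 125, seed = seed)
stats <- size_distribution_stats(g$diameters_nm, bin_width_nm = 25)
write.csv(stats$histogram, file.path(out_dir, "diameter_histogram.csv"),
          row.names = FALSE)
cat(sprintf("\nDiameter table (n = %d): fitted mode %.1f nm, FWHM %.1f nm\n",
            stats$n, stats$peak_nm, stats$fwhm_nm))
cat("Tables written under", out_dir, "\n")
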