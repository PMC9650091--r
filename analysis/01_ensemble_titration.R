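#!/usr/bin/env Rscript
# Ensemble FRET titration: emission spectra of DiI-DiD vesicles across a
# sorbitol-like crowder series, converted to apparent E_FRET and mean dye
# separation, with the quadratic heuristic trend.
#
# A crowder that compacts the vesicles shortens the mean inter-dye
# distance, so E_FRET rises and R falls monotonically with concentration.
# The synthetic series is generated so that R runs from 5.02 nm (no
# crowder) to 4.76 nm (3 M), the range the ensemble assay spans.

library(luvfret)

out_dir <- file.path("results", "01_ensemble_titration")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 101

conc_M <- c(0, 0.5, 1, 1.5, 2, 2.5, 3)
r_true <- seq(5.02, 4.76, length.out = length(conc_M))
e_true <- distance_to_efficiency(r_true)

in_dir <- file.path(out_dir, "spectra")
dir.create(in_dir, showWarnings = FALSE)
files <- vapply(seq_along(conc_M), function(i) {
  write_synthetic(
    simulate_spectrum(e_true[i], total_area = 1e4, noise_sd = 2,
                      seed = seed + i),
    file.path(in_dir, sprintf("sorbitol_%03.1fM.csv", conc_M[i])))
}, character(1))

res <- run_pipeline(run_config(
  "titration",
  data.frame(file = files, concentration = conc_M, replicate = 1),
  seed = seed, output_dir = out_dir))

tab <- res$efret_table
cat("\nE_FRET and mean separation across the titration:\n")
print(tab[, c("concentration", "efret", "r_nm")], digits = 4)
cat(sprintf("\nRecovered E within %.4f of truth at every concentration\n",
            max(abs(tab$efret - e_true))))
cat("Quadratic trend in E_FRET (c0, c1, c2):",
    signif(res$trend$efret$coefficients, 4), "\n")
cat("Separation shrinks from", round(tab$r_nm[1], 2), "to",
    round(tab$r_nm[nrow(tab)], 2), "nm -> compaction signature\n")
cat("Tables written under", out_dir, "\n")
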