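# luvfret

Quantitative analysis of crowding-induced compaction of submicron lipid
vesicles, read out through membrane FRET.

Large unilamellar vesicles (~200 nm) carrying the lipophilic FRET pair
DiI (donor) and DiD (acceptor) report on their own geometry: when a
molecular crowder (sorbitol, PEG, Ficoll) compacts the vesicle, the mean
dye separation ⟨d⟩ shrinks and the apparent transfer efficiency

    E = I_A / (I_A + I_D),        E = R0^6 / (R0^6 + R^6),   R0 = 5.3 nm

rises. The package implements the four analyses such an assay rests on,
for spectroscopists and single-molecule microscopists who want the whole
chain in scriptable, tested form:

* **Ensemble spectra** (`integrate_bands()`, `series_to_efret()`,
  `fit_titration_quadratic()`) — band-integrated emission spectra across a
  crowder titration → E_FRET and ⟨d⟩ per concentration with a quadratic
  trend.
* **TCSPC lifetimes** (`fit_reconvolution()`, `bootstrap_lifetimes()`) —
  multi-exponential decays fitted by iterative reconvolution with the IRF
  over the excitation period, amplitude-weighted lifetime
  τ_av = Σaᵢτᵢ/Σaᵢ, parametric-bootstrap confidence intervals.
* **Dynamic light scattering** (`fit_correlogram()`,
  `stokes_einstein_diameter()`, `size_distribution_stats()`) —
  G(τ) = A[1 + B·exp(−2Dq²τ)] inverted to hydrodynamic diameter via
  Stokes–Einstein; log-normal summaries for diameter tables.
* **Single-vesicle TIRF imaging** (`split_and_register()`,
  `detect_spots()`, `extract_traces()`, `build_histogram()`,
  `compare_conditions()`, or `analyze_movie()` for the whole chain) —
  dual-view movies → registered channels → per-vesicle E_FRET →
  0.01-bin histograms with Gaussian peak fits → before/after/wash
  reversibility verdicts.

Every input modality has a seed-deterministic synthetic generator
(`simulate_spectrum()`, `simulate_decay()`, `simulate_correlogram()`,
`simulate_movie()`, ...) with serialized ground truth, so the full chain
is testable without instrument data. `run_pipeline()` drives any of the
four workflows from a manifest (or YAML config) and writes audited output
directories. The numbered scripts under `analysis/` are narrative drivers
for the four studies; `vignettes/vesicle-compaction-methods.Rmd` documents
the models, defaults and limitations.

## Worked example

```r
library(luvfret)

# one tethered-vesicle field imaged before / after / during wash-out of a
# high-molecular-weight crowder (true E: 0.40 -> 0.60 -> 0.40)
field <- simulate_vesicle_field(field_um = c(18, 18), seed = 3)
hists <- lapply(c(before = 0.40, after = 0.60, wash = 0.40), function(e) {
  sim <- simulate_movie(field, efret = e, n_frames = 60, seed = 3)
  analyze_movie(sim$movie)$histogram
})
hists$after
#> E_FRET histogram: 43 vesicles in 0.01-wide bins; Gaussian peak 0.594 (sd 0.001), <d> = 4.97 nm
cmp <- compare_conditions(hists$before, hists$after, hists$wash)
cmp$verdict
#> [1] "reversible"
round(cmp$peaks, 3)
#> before  after   wash
#>  0.394  0.594  0.394
```

The histogram peak is the fitted center of the per-vesicle efficiency
distribution (within 0.006 of the simulated truth here); `<d>` converts it
through the Förster relation; the verdict says the crowder-induced peak
shift (0.394 → 0.594, far beyond the 0.03 threshold) relaxed back on
washing — the signature of an excluded-volume effect rather than a
permanent membrane change.

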