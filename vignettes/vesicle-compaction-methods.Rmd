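---
title: "Methods: quantifying crowding-induced vesicle compaction from FRET, lifetime, scattering and single-vesicle imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying crowding-induced vesicle compaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luvfret)
```

## The measurement problem

Large unilamellar vesicles (LUVs, ~100–1000 nm) carrying the lipophilic
FRET pair DiI (donor) and DiD (acceptor) in their bilayer report on their
own geometry: when the vesicle compacts, the mean donor–acceptor
separation $\langle d \rangle$ shrinks and the transfer efficiency rises.
Four independent readouts probe this, and `luvfret` implements the
quantitative analysis for each:

1. **Ensemble emission spectra** across a crowder titration →
   apparent $E_\mathrm{FRET}$ and $\langle d \rangle$ per concentration.
2. **TCSPC lifetime decays** → donor quenching as a decrease of the
   amplitude-weighted lifetime $\tau_{av}$.
3. **Dynamic light scattering** → hydrodynamic diameter $d_H$.
4. **Dual-view TIRF movies of single tethered vesicles** → per-vesicle
   $E_\mathrm{FRET}$ histograms and a before/after/wash reversibility
   verdict.

Because the raw instrument data are not required for development or
testing, every modality has a seed-deterministic synthetic generator with
serialized ground truth; all recovery claims in this vignette are the ones
the test suite and `scripts/acceptance.R` actually compute.

## FRET arithmetic

Apparent efficiency is the uncorrected proxy
$E = I_A / (I_A + I_D)$ — no gamma factor, spectral leakage or
direct-excitation correction, matching how the assay is read out.
Correction hooks exist on `fret_params()` but default to the identity.
Distances use the Förster relation with $R_0 = 5.3$ nm for DiI–DiD:

$$E = \frac{R_0^6}{R_0^6 + R^6}, \qquad
  R = R_0\left(\frac{1-E}{E}\right)^{1/6}.$$

The two maps are exact algebraic inverses (round trip to $10^{-12}$
relative, a tested property). Note a rounding subtlety: a histogram peak
printed as $E = 0.6$ maps to 4.95 nm, which reports as 4.9 or 5.0
depending on where the unrounded peak sat; the package returns the
unrounded value and leaves presentation to the caller.

## Ensemble spectra

Band integration uses trapezoidal quadrature on the native wavelength grid
(no resampling). The integration windows are not standardized on the
instrument, so the defaults are a design choice: donor 545–610 nm, acceptor
650–750 nm, consistent with DiI/DiD emission and the 640 nm dichroic used
in imaging; both are arguments. Background handling accepts a measured
blank spectrum or a constant; by default the median intensity over
750–780 nm (past the acceptor tail) is subtracted. Spectra with zero total
band signal are flagged and excluded from trend fits rather than
propagating `NaN`. The concentration trend is summarized with the
assay's heuristic: an ordinary least-squares quadratic.

The generator renders donor/acceptor lines as skew-normal templates
(location/scale/shape 556/12/4 and 661/14/4 nm) whose areas split
$(1-E)\!:\!E$. The templates put >99.8 % of each line inside its band, so
band integration recovers $E$ to better than 0.005 — the generator
emulates clean, crosstalk-free spectra, which is precisely what the
apparent-efficiency estimator assumes; real DiI/DiD spectra have a few
percent of spectral overlap that this pipeline deliberately does not
unmix.

## TCSPC reconvolution

The decay model is a sum of exponentials under periodic excitation. Each
component is wrapped over the repetition period $T$ (12.5 ns at 80 MHz;
50 ns at 20 MHz) so incomplete decay from earlier pulses is included:

$$d(t) = \sum_i a_i \frac{e^{-t/\tau_i}}{1 - e^{-T/\tau_i}},$$

sampled at bin centers, circularly convolved (FFT) with the
unit-normalized IRF, shifted by a sub-bin timing offset (linear
interpolation, bounded to ±5 bins), plus a constant background. Bin-center
sampling makes the discrete count sum match the analytic
$\sum_i a_i \tau_i / \Delta t$ to $O((\Delta t/\tau)^2)$, a tested
conservation property.

Fitting is Levenberg–Marquardt least squares over amplitudes,
log-lifetimes, background and shift, from the first bin reaching 1 % of
the peak to the end of the record. **Weighting** is Poisson with the
variance taken from the *model* counts, re-evaluated every iteration.
The more common shortcut of weighting by the observed counts was measured
here to bias lifetimes upward by ~0.6 % at $10^4$ peak counts and to
flatten the objective into near-degenerate local optima; with model-based
weights the optimum is unique (cold and warm starts agree) and the bias
disappears. This matters because confidence intervals come from a
parametric bootstrap (Poisson resampling of the fitted model, 2.5/97.5
percentile intervals): with observed-count weights the intervals covered
the truth in only ~76 % of runs, with model-based weights coverage is
96–98 % at nominal 95 %.

Degenerate models are handled explicitly: lifetimes closer than 5 %
relative are merged and the fit re-run with one component fewer, and a
component driven to a sub-bin lifetime or vanishing amplitude (the
signature of an over-specified model) is pruned the same way. Component
count is user-specified (1–4); there is no automatic model selection.

The recovery study (`tcspc_recovery_study()`) uses the acquisition
condition of $10^4$ counts at the decay maximum, a 0.2 ns FWHM Gaussian
IRF, and the reference biexponential (0.6 of 0.5 ns + 0.4 of 2.0 ns) on a
512-bin grid: median lifetime errors are well under 1 %, $\tau_{av}$
error ~0.3 %.

## Dynamic light scattering

The correlogram model is the single-exponential form used on the
backscatter instrument,

$$G(\tau) = A\left[1 + B e^{-2 D q^2 \tau}\right], \qquad
  q = \frac{4\pi n}{\lambda_0}\sin(\theta/2),$$

with $\lambda_0 = 633$ nm, $\theta = 178°$, $n = 1.33$, fitted by
constrained nonlinear least squares ($A, B, D > 0$, $B \le 1.2$).
Initialization follows the curve itself: $A$ from the tail mean, $B$ from
the intercept, $D$ from a log-linear fit of the early decay. No cumulant
expansion or regularized inversion is attempted — distribution width is
obtained from repeated measurements, as in standard practice for this
instrument class. $d_H = k_B T / (3\pi\eta D)$ with environment defaults
T = 298.15 K and η = 8.9×10⁻⁴ Pa·s (water at 25 °C), both arguments since
neither is standardized.

Size tables (from electron micrographs, measured elsewhere) are
summarized by `size_distribution_stats()`: a fixed-width histogram (25 nm
bins by convention), a closed-form log-normal MLE, and the fitted mode and
FWHM — the two numbers such histograms are reported in.

## Single-vesicle imaging

The dual-view frame is split along the configured axis; the inter-channel
translation is estimated by FFT cross-correlation of the time-averaged
channels with parabolic sub-pixel refinement, and the acceptor stack is
resampled onto the donor grid by bilinear interpolation. Translation-only
registration is sufficient at the scale of a two-channel image splitter;
an affine extension was considered and deliberately left out. A
correlation peak below 0.2 (normalized) raises a registration error
carrying the identity transform.

Spot detection runs on the *sum* of the registered channels, so vesicles
pushed toward either channel by FRET are not missed: difference-of-
Gaussians band-pass matched to the PSF, local maxima above
median + k·MAD (k = 5), minimum-separation enforcement (brightest wins),
center-of-mass sub-pixel refinement. Traces integrate a circular aperture
(radius 3 px) minus the annulus median (5–7 px) scaled by aperture area,
per channel per frame. Per-vesicle $E$ is the ratio of trace means over a
configurable frame range (default: all frames; no photobleaching
truncation, since one efficiency per vesicle per condition is the
readout).

Histograms use fixed 0.01-wide bins on [0, 1] and a least-squares
Gaussian fit to the bin counts, initialized at (argmax bin, 0.05,
max count); the fit is withheld if its RMS residual exceeds half the peak
count, and with fewer than 10 vesicles no fit is attempted.
`compare_conditions()` turns three fitted peaks into the assay's verdict:
a peak shift beyond the threshold (default 0.03) on crowder addition that
persists after washing is *irreversible*, one that relaxes back is
*reversible*, anything else is *no effect*. The mean total intensity per
vesicle is checked alongside (flag at >20 % change): a peak shift with
conserved total intensity indicates compaction, not dye loss or rupture.

### What the movie generator emulates — and what it does not

`simulate_movie()` renders immobile, surface-tethered vesicles: Poisson
vesicle count at the observed tethering density (195 per 25×50 µm),
uniform positions with ~1 µm minimum separation, log-normal total
brightness (σ = 0.4, matching the visibly log-normal intensity
histograms of tethered vesicles), brightness split $(1-E)\!:\!E$ between
channels, pixel-integrated Gaussian PSF (σ = 1.2 px at 0.11 µm/px), a
true inter-channel shift, uniform background (5 photons/px/frame), Poisson
shot noise and a camera model (offset 100, read noise σ = 2, unity gain).
Per-vesicle total brightness is drawn once per field and reused across
conditions — the same flow cell is imaged before/after/wash — which makes
total-intensity conservation exact in the ground truth and a sensitive
pipeline check (recovered totals agree across conditions to <1 %).

Not modeled: blinking, photobleaching, FRET dynamics within a trace,
vesicle diffusion (tethered ⇒ immobile), chromatic aberration beyond a
translation, and the dye-copy-number statistics that set the real
per-vesicle $E$ dispersion (the generator exposes $E$ as a constant or a
user distribution instead). Passing tests therefore demonstrate that the
pipeline is unbiased and internally consistent under these idealized
conditions, not that it is robust to every artifact of real recordings.

## Problem sizes and numerical choices

The study-scale runs used by the acceptance checks are: 50 synthetic
decays × 100 bootstrap replicates (TCSPC), 20 correlograms at each of
100/227/400/1000 nm with 1 % noise (DLS), and two before/after/wash trios
of 500-frame movies over a 36×36 µm field (~200 vesicles at the tethering
density, the count a field of view holds). Histogram peaks are recovered
within 0.005 of the true $E$; the residual bias comes from the slightly
different aperture capture of the bilinearly resampled acceptor channel
and sits well inside the 0.02 the assay needs to resolve its smallest
reported shift (0.40 → 0.42).

Other numerical choices: all optimizations are bounded Levenberg–
Marquardt (`minpack.lm`); lifetimes are fitted in log space; RNG state is
always saved and restored around seeded generators, so library calls
never perturb a caller's stream; generators are bit-identical under a
fixed seed (tested).

## Known limitations

* Apparent efficiencies only; absolute distances inherit any error in
  $R_0$ and in the uncorrected proxy ratio.
* The DLS inversion is strictly monodisperse; strongly polydisperse
  samples need cumulant or regularized methods out of scope here.
* Registration is translation-only; rotation or magnification mismatch
  between channels would bias acceptor photometry.
* The Gaussian histogram fit assumes a unimodal population; mixed vesicle
  populations would need a mixture model.
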