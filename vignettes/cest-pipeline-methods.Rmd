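---
title: "Models and methods behind cestpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cestpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestpipe)
```

# The measurement problem

Chemical exchange saturation transfer (CEST) MRI detects dilute
metabolites through their exchangeable protons: a long, frequency-
selective RF pulse saturates the solute protons, exchange carries the
saturation into the bulk water pool, and the water signal drops. For
hydroxyl protons (myoinositol and other glial sugars/alcohols) the
relevant resonance sits only ~0.6 ppm from water and exchanges at
k ≈ 600 s⁻¹, so the measured contrast — the asymmetry of the normalized
z-spectrum about the water line,

MTR_asym(Δω) = 100 · (M_sat(−Δω) − M_sat(+Δω)) / M₀ ,

is small, rides on a steep direct-saturation background, and is acutely
sensitive to B0 (water frequency) errors. `cestpipe` implements the full
quantitative chain for a paired-injection neuroinflammation experiment:
z-spectrum simulation, WASSR B0 mapping, B0-corrected MTR_asym ROI
statistics with a QC gate, Iba-1 soma morphometry, MRS metabolite QC,
and paired group statistics — plus synthetic generators for every input,
so each stage is testable against known ground truth.

# Multi-pool Bloch-McConnell simulation

`simulate_zspectrum()` integrates the coupled Bloch-McConnell equations
for N proton pools (water first). For pool *i* with relaxation rates
R1ᵢ = 1/T1ᵢ, R2ᵢ = 1/T2ᵢ, offset Δωᵢ from the RF frequency, RF
amplitude ω₁ = 2π·γ̄·B1, and exchange to water at kᵢ:

- dMxᵢ/dt = −(R2ᵢ+kᵢᵒᵘᵗ)Mxᵢ + Δωᵢ Myᵢ + inflow
- dMyᵢ/dt = −Δωᵢ Mxᵢ − (R2ᵢ+kᵢᵒᵘᵗ)Myᵢ + ω₁Mzᵢ + inflow
- dMzᵢ/dt = −ω₁Myᵢ − (R1ᵢ+kᵢᵒᵘᵗ)Mzᵢ + R1ᵢM0ᵢ + inflow

Detailed balance fixes the reverse (water→solute) rate at fᵢ·kᵢ, where
fᵢ is the pool's equilibrium fraction, so thermal equilibrium is a
fixed point of the exchange operator — this is asserted in the tests,
not assumed.

Because the hard saturation pulse has constant amplitude, the system is
linear with constant coefficients. Two solution modes are exposed:

- `steady_state`: the fixed point −A⁻¹b (the infinite-duration limit);
- `time_evolved` (default): the exact propagator
  M(t) = M_ss + e^{At}(M₀ − M_ss), evaluated by eigendecomposition with
  a scaling-and-squaring fallback. This is preferred over a generic
  stiff ODE integrator because it is exact to machine precision, has no
  tolerance to tune, and is two orders of magnitude faster — which the
  voxelwise phantom generator relies on. An entirely independent
  fixed-step RK4 integrator lives in the test suite as a brute-force
  oracle for the propagator, and the closed-form single-pool CW
  saturation curve (`single_pool_cw_oracle()`) pins the zero-solute
  limit to 10⁻⁶ relative accuracy.

Each offset is simulated independently from thermal equilibrium;
readout, recovery delays and B1 inhomogeneity are not modeled, and the
macromolecular pool uses a Lorentzian (not super-Lorentzian) lineshape.

## Default pool parameters

No published pool table exists for this experiment, so
`default_pools()` ships *plausible* values for mouse brain at 9.4 T,
clearly labeled as such: water (T1 1.8 s, T2 40 ms), a hydroxyl pool at
+0.6 ppm with k = 600 s⁻¹ (f = 0.002, lumping the several -OH
contributors), and a broad macromolecular-like pool at −2.4 ppm
(T2 0.5 ms, f = 0.005, k = 30 s⁻¹). With the 1.6 s / 0.9 µT saturation
pulse these produce MTR_asym(0.6 ppm) ≈ 5.4%, in the range reported for
in vivo hippocampus, and doubling the hydroxyl fraction raises it to
≈ 10.3%. All analysis functions take pools explicitly; the defaults only
seed examples and the synthetic cohort.

# WASSR B0 mapping

The WASSR acquisition (0.5 s / 0.1 µT prepulse, 35 offsets in ±1 ppm)
produces a narrow direct-saturation dip whose center is the voxel's
true water frequency. `fit_voxel_shift()` implements the
maximum-symmetry estimator: spline-interpolate to a 0.001 ppm grid,
score candidate centers on a 0.005 ppm coarse grid by the mean squared
difference between the spectrum and its mirror image (only over the
symmetric overlap with the sampled range, to avoid extrapolation bias),
and refine the minimum parabolically. Candidates at the search boundary
and non-finite or flat spectra are flagged invalid rather than fitted.

One numerical detail matters: at 35-offset sampling a cubic spline of
the raw dip aliases, limiting noiseless accuracy to ≈ 0.0055 ppm. The
interpolation is therefore performed on u = Z / max(1−Z, 0.05), which
for a CW-saturated single pool is exactly quadratic in the offset, and
back-transformed before the symmetry score. Since this is a monotone
pointwise map of the values, it preserves mirror symmetry — the
estimator remains unbiased on symmetric spectra for any relaxation
times (tested over a T1/T2 sweep) — while the cap bounds noise
amplification where Z → 1. Measured performance: ≤ 0.001 ppm noiseless
voxelwise, ≈ 0.003 ppm median error at noise SD 0.02.

`qc_roi_pair()` applies the study's B0 homogeneity gate: a subject's
CEST data are used only when the two analysis ROIs' mean B0 estimates
differ by at most 0.05 ppm (difference of ROI means; medians behind a
flag). The measured difference is always reported, and an ROI with no
valid voxel fails with reason `"unmeasurable"`.

# Z-spectrum processing and MTR asymmetry

Per voxel, the processing order is fixed: normalize by M₀
(`normalize_stack()`, with an intensity threshold mask), interpolate
with a natural cubic spline (no smoothing), translate the frequency
axis by −shift to re-center the water dip (`b0_correct()`), and
evaluate MTR_asym (`mtr_asym()`, percent). `mtr_asym_map()` composes
these per valid voxel. Correction before asymmetry (rather than the
reverse) keeps the round-trip property testable: correcting with the
true shift at node-aligned shifts reproduces the unshifted spectrum
exactly.

## Known limitation: resampling bias at 0.2 ppm sampling

With offsets every 0.2 ppm, both the direct-saturation walls and the
exchange-broadened hydroxyl feature ((k + R2)/π ≈ 212 Hz ≈ 0.53 ppm
FWHM at 9.4 T) are only marginally sampled. Re-evaluating the spectrum
at positions displaced by a B0 shift therefore biases the recovered
asymmetry by up to ≈ 0.4 percentage points at worst-case shifts
(|s| ≤ 0.3 ppm, noiseless), periodically in the shift with period
0.2 ppm and vanishing at node-aligned shifts. We quantified this floor
across interpolants (natural spline, rational barycentric, trigonometric,
local Hermite, Lorentzian-baseline hybrids): none achieves better than
≈ 0.13 points worst-case, so the field-standard natural cubic spline is
retained and the bias is documented instead of hidden. It is immaterial
for the group contrast (≈ 5 points) but matters when sub-0.1-point
absolute accuracy is required; acquiring finer offset sampling around
±0.6 ppm is the real remedy.

# Synthetic data generators

All generators are pure functions of (spec, seed) — they restore the
caller's RNG state — and return the ground truth needed to score every
downstream stage.

- `make_cest_phantom()` renders CEST and WASSR stacks on the emulated
  readout geometry (20×20 mm FOV, 128×128 matrix): per voxel the
  simulated spectrum of its solute-fraction multiplier evaluated at
  offsets shifted by a smooth polynomial B0 field (plus an optional
  Gaussian "susceptibility artifact" bump and a constant lesion-ROI
  offset used as a QC fixture), scaled by M₀ = 1000 with additive
  Gaussian noise (SD as a fraction of M₀; Gaussian is adequate at the
  simulated SNR and keeps the oracles analytic — Rician magnitude noise
  is not modeled). The default offset schedules are 41 points at 0.2 ppm
  in ±4 ppm and 35 uniform points in ±1 ppm; since "40 offsets between
  ±4 ppm at 0.2 ppm intervals" is arithmetically ambiguous about 0 ppm,
  the schedule is an explicit argument everywhere.
- `make_slide()` draws dark elliptical somata (areas in µm², normal
  with mean 40 / SD 8, truncated; non-overlapping by rejection
  sampling) with thin radial processes as distractors, on a smooth
  bright background with an uneven-staining gradient, plus pixel noise.
  Geometry is drawn in physical units before rasterization, so one seed
  yields the same slide at any pixel size (0.46 µm/px default, a 20×
  scan). Ground-truth soma areas are the rasterized ellipse areas;
  processes are not part of the truth — the segmenter must reject them.
- `make_metabolite_table()` emulates an LCModel concentration table:
  per subject and side, seven metabolites with log-normal concentration
  noise (the reported CRLB %SD), a per-spectrum linewidth
  (N(12.9, 0.8) Hz), a configurable LPS-side myoinositol effect, and
  optional injected QC violations. Baselines put the vehicle-side
  mI/tCr at ≈ 0.70 so the default +17% effect yields ≈ 0.82.

What the generators do *not* emulate: anatomically realistic geometry,
partial volume, Rician noise, scanner drift, motion, or stain color —
so green tests demonstrate algorithmic correctness on idealized data,
not robustness to those real-world effects.

# Soma morphometry

`segment_somata()` follows the classic recipe for uneven background:
small mean-filter blur (5 px), local background estimate by a large
mean filter (75 px, several soma diameters), foreground where the
blurred image falls more than 25% below the local background, connected
components, and a size gate (12–150 µm²) that rejects thin processes
and fused clumps. A global-threshold mode is retained purely as a
negative control — on a strong staining gradient it loses the somata on
the dark side, which the adaptive threshold does not. Interactive
"inspect and correct" workflows are externalized as an `edits` list of
region ids to drop, so corrections are data, not clicks. The blur
window, offset fraction and size bounds are configuration with
documented defaults; they were chosen on the synthetic fixtures and
validated by recovery (≥ 90% detection, median area within 10%,
+10 µm² shift recovered within ±2 µm²).

`roi_soma_stats()` uses a centroid rule (a soma belongs to the ROI
containing its centroid), so tangent ROIs partition somata without
double counting. `soma_size_difference()` computes the study's
activation marker — per-slice LPS − PBS difference of median soma
areas, summarized per animal as median (IQR) — and `classify_iba1()`
turns it into a responder call (majority of slices above a 0 µm²
threshold). That rule is a documented surrogate for the pathologist's
judgment, not a validated diagnostic.

# Statistics and the study driver

`paired_compare()` reports per-side medians with 25th–75th percentile
IQRs (linear interpolation) and three tests: the paired t-test, the
Wilcoxon *signed-rank* test on paired differences, and the two-sample
Wilcoxon rank-sum statistic. The named nonparametric test for this
paired design is ambiguous in common usage; the signed-rank test is the
paired analogue, so it is primary and the rank-sum value is reported
alongside, both labeled. No multiple-testing correction is applied
(matching the emulated analysis); with fewer than 3 pairs only
descriptives are returned, and degenerate inputs flag the affected
p-value as NA. Type-I calibration at n = 6 is verified by simulation
(2000 null replicates, rejection rate within 5% ± 2 points).

`run_study()` runs the whole chain per subject — phantom (or, in a
real study, loaded stacks), WASSR B0 map restricted to the two ROIs,
B0 gate, asymmetry ROI means, MRS QC and creatine ratios, slide
segmentation and soma differences — and assembles paired outcome
tables, group tests, an exclusion log with machine-readable reasons,
a responder classification table and boxplot-ready long-format data.
Every component seed derives from one master stream, so no two
generator calls share a seed and the whole report is reproducible from
a single integer.

Two cohort design choices deserve note. First, the default cohort (6
"effect" subjects with doubled lesion-ROI hydroxyl fraction, +10 µm²
LPS-side soma shift and +17% LPS-side myoinositol; 6 "null" subjects
with no injected effect; 5% between-subject log-normal jitter; phantom
noise SD 0.01) is the package's canonical test condition. Second, the
LPS and PBS hemispheres of one slice share their soma-layout seed
(`paired_slides = TRUE`): the per-slice difference is a within-slice
contrast in the real experiment, and the shared layout emulates that
correlation; with fully independent sides (available via
`paired_slides = FALSE`) the null group's per-slice difference sign is
a coin flip, which no threshold rule could classify.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: 41/35-offset schedules
on 6×6 to 32×32 phantom grids (full 128×128 in the cohort run, with B0
fitting restricted to the ROIs), 200 replicates for the noisy WASSR
benchmark, 500 for the power check, 2000 for type-I calibration,
512×512 px slides with 50 somata, and a 12-subject cohort. A full
`run_study()` takes well under a minute on one core;
`scripts/acceptance.R` recomputes every headline quantity from scratch
in about half a minute.
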