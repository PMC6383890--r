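# cestpipe

Quantitative analysis pipeline for CEST-MRI studies of
neuroinflammation, with paired histology morphometry and MRS quality
control.

## The problem

Hydroxyl CEST imaging detects glial metabolites such as myoinositol
through chemical exchange: a long, weak RF pulse saturates the -OH
protons (~0.6 ppm from water, exchanging at k ≈ 600 s⁻¹) and the
saturation transfers to the water signal. The contrast is the asymmetry
of the normalized z-spectrum Z(Δω) = M_sat/M₀ about the water line,

```
MTR_asym(Δω) = 100 · ( M_sat(−Δω) − M_sat(+Δω) ) / M₀   [%]
```

evaluated at Δω = 0.6 ppm. At that offset the signal rides on a steep
direct-saturation background and a B0 error of a few hundredths of a
ppm corrupts the asymmetry, so a typical paired-injection experiment
(LPS in one hippocampus, vehicle contralaterally) needs: a multi-pool
Bloch-McConnell simulator to choose saturation parameters, WASSR
water-frequency mapping with the maximum-symmetry algorithm, a B0
homogeneity gate (ROI difference ≤ 0.05 ppm), B0-corrected MTR_asym
maps averaged over 1.25 × 1.25 mm ROIs, Iba-1 soma morphometry to
classify responders, LCModel-style metabolite QC (linewidth ≤ 25 Hz,
CRLB < 10%, ratios to total creatine), and paired statistics reported
as median (IQR) with paired t and Wilcoxon tests.

`cestpipe` implements that chain end to end, plus synthetic generators
(phantom CEST/WASSR stacks with known B0 fields and solute maps,
histology slides with known soma areas, metabolite tables with known
effects) so that every stage is validated against ground truth — the
package targets methodologists and preclinical imaging groups who need
a tested, reproducible reference implementation rather than one-off
scripts.

## Worked example

```r
library(cestpipe)

# Three-pool system (water, hydroxyl at +0.6 ppm with k = 600 /s,
# broad macromolecular pool) under the 1.6 s / 0.9 uT hard pulse:
pools <- default_pools()
z <- simulate_zspectrum(pools, saturation_pulse(b1 = 0.9, duration = 1.6),
                        default_cest_offsets(), scanner_context())
mtr_asym(z, delta = 0.6)
#> [1] 5.381939
```

The asymmetry at 0.6 ppm is 5.4% — the exchange-weighted contrast the
solute pool contributes on top of the (symmetric) direct saturation.

```r
# WASSR: recover a +0.12 ppm water-frequency shift from a 35-offset
# low-power acquisition with the maximum-symmetry estimator:
zw <- simulate_zspectrum(pools, saturation_pulse(0.1, 0.5),
                         default_wassr_offsets() - 0.12, scanner_context())
fit_voxel_shift(zspectrum(default_wassr_offsets(), zw$values))$shift
#> [1] 0.1199413
```

```r
# Full synthetic study: 6 responders (doubled lesion-ROI solute,
# +10 um^2 LPS-side soma shift, +17% LPS-side mI) and 6 non-responders.
report <- run_study(cohort_spec(), seed = 1)
print(report)
#> <study_report> status=ok, 12 subjects, 0 exclusions
#>   effect.mtr_asym    n=6 median LPS 10.3 PBS 5.51  t p=3.99e-06  W p=0.0313
#>   effect.mi_tcr      n=6 median LPS 0.816 PBS 0.692  t p=0.006  W p=0.0313
#>   effect.soma_diff   n=6 median LPS 9.2 PBS 0  t p=4.4e-08  W p=0.0313
#>   null.mtr_asym      n=6 median LPS 5.72 PBS 5.52  t p=0.365  W p=0.313
#>   null.mi_tcr        n=6 median LPS 0.666 PBS 0.718  t p=0.108  W p=0.219
#>   null.soma_diff     n=6 median LPS 0 PBS 0  t p=NaN  W p=NaN
```

The responder group shows the expected pattern — elevated LPS-side
MTR_asym (10.3% vs 5.5%), elevated mI/tCr (0.82 vs 0.69) and a positive
soma-size difference — while the null group shows none; `report$subjects`
holds the per-animal values, `report$exclusions` the QC log, and
`report$boxplot_data` plotting-ready long-format data.

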