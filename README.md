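# lsamorph

Morphometry of lenticulostriate arteries (LSAs) from binary vessel
delineations.

LSAs are the small perforating arteries that branch from the middle
cerebral artery and supply the basal ganglia — territory whose perfusion
depends entirely on these vessels, and where small vessel disease begins.
Because they are too small for routine angiography, LSAs are studied on
thin-slab minimum intensity projections of black-blood MRI: a reader
delineates each vessel, and quantitative shape measures are computed from
the delineation's skeleton. `lsamorph` implements that measurement chain
end to end, for researchers quantifying perforating-artery morphology in
aging and cerebrovascular cohorts:

- **Centerline extraction** — thin-slab minIP for 3D inputs, Zhang–Suen
  skeletonization with staircase sparsification, iterative spur pruning,
  and longest-geodesic path extraction with anisotropic mm spacing.
- **Per-vessel morphometry** — vessel length (VL, the path length
  *L<sub>A</sub>*), chord length *L<sub>C</sub>*, distance metric
  DM = *L<sub>A</sub>*/*L<sub>C</sub>*, and the composite vessel
  tortuosity index

  **VTI = 0.1 · SD<sub>θ</sub> · N · M · L<sub>A</sub>/L<sub>C</sub>**

  where SD<sub>θ</sub> is the standard deviation of tangent angles along
  the centerline, *N* the number of critical points (slope sign changes),
  and *M* the mean arc/chord ratio between consecutive inflection points.
  VTI is 0 exactly for straight vessels and unbounded above.
- **Subject summaries and cohort statistics** — LSA count plus
  mean/median/SD of each metric per subject; covariate-adjusted ANCOVA
  group comparisons, partial Spearman correlations, χ² tests, Bonferroni
  correction within comparison families, and absolute-agreement ICC for
  rater consistency.
- **Synthetic data** — analytic curve families with closed-form/quadrature
  ground truth, rasterized vessel phantoms with optional spur noise, and
  simulated cohorts with configurable prevalences, standardized effect
  sizes and copula-induced Spearman correlation targets, so every stage
  is testable without scan data.

## Worked example

Generate a known curve, rasterize it like a manual delineation, and
measure it back:

```r
library(lsamorph)

gc   <- generate_curve(curve_spec("sinusoid", chord_length = 20,
                                  amplitude = 2, wavelength = 10))
mask <- rasterize_curve(gc$centerline, spacing = c(0.44, 0.44))
cl   <- mask_to_centerline(mask)       # skeletonize -> prune -> extract
tortuosity_metrics(cl)
#>   vl_mm chord_mm    dm sd_theta_deg n_critical magnitude   vti
#> 1 25.86     19.8 1.306        37.96          4     1.288 25.53

gc$ground_truth[c("arc_length", "dm_true")]
#> $arc_length 26.413   $dm_true 1.3207
```

The measured vessel length (25.86 mm) and DM (1.306) sit within ~2% and
~1% of the analytic ground truth for this two-period sinusoid; the four
critical points are its four interior extrema, and the VTI of ~26
reflects substantial tortuosity (a straight vessel scores exactly 0).

Simulate a cohort with the default emulation targets (n = 125,
hypertension 40.8%, smoking 28.8%, median LSA count 8) and run the full
adjusted analysis grid:

```r
tab <- generate_cohort(effect_config(seed = 1))
res <- run_full_analysis(tab)
head(res[order(res$p_raw), ], 3)
#>               comparison effect statistic    p_raw p_adjusted   n            family
#> 14 smoking -> vti_median -0.476     12.13 0.000694     0.0111 125 risk_factor_anova
#> 47       pca ~ dm_median  0.283      3.23 0.001593     0.0558 125 diameter_spearman
#> 48        pca ~ vti_mean  0.250      2.83 0.005520     0.1932 125 diameter_spearman
```

The top hit recovers the injected smoking effect on median VTI (adjusted
group-mean difference −0.48, Bonferroni-corrected p = 0.011 within the
16-comparison risk-factor family); the PCA–tortuosity correlations are the
copula targets showing through at n = 125.

A command-line wrapper over the same functions lives at
`inst/cli/lsamorph.R`:

```sh
Rscript inst/cli/lsamorph.R full --out-dir out --seed 1
```

## Documentation

The methods vignette (`vignettes/lsa-morphometry.Rmd`) describes the
measurement model and its assumptions, the open design choices (frame
alignment, angle units, the aggregation of *M*, spur and jitter
thresholds), what the synthetic cohort does and does not emulate, and the
package's validation scale and known limitations.
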