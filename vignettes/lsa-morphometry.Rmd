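---
title: "Quantifying lenticulostriate artery morphology from vessel delineations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lenticulostriate artery morphology from vessel delineations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsamorph)
```

## The problem

Lenticulostriate arteries (LSAs) are small perforating vessels that branch
from the middle cerebral artery (MCA) and supply the basal ganglia. Their
number, length and tortuosity are candidate imaging biomarkers of cerebral
small vessel degeneration. In practice they are visualized on thin-slab
minimum intensity projections (minIP) of black-blood MRI, delineated
manually, and measured on the skeleton of the delineation. `lsamorph`
implements that measurement chain — delineation mask to centerline to
per-vessel metrics to per-subject summaries to covariate-adjusted cohort
statistics — together with a synthetic-data module that generates analytic
curves and simulated cohorts, so the whole pipeline is testable without any
scan data.

## From mask to centerline

A delineation arrives as a binary raster with physical pixel spacing
(NIfTI, where the spacing travels in the header, or PNG with a YAML
sidecar). Three steps produce the measurable object:

1. **Skeletonization** (`skeletonize()`): Zhang–Suen iterative thinning
   followed by a sequential simple-point sparsification pass. The second
   pass removes the staircase-redundant pixels that parallel thinning
   leaves behind, so the result is a minimal 8-connected skeleton. We use
   8-neighbor connectivity throughout because manual tracing routinely
   produces one-pixel diagonal strokes that 4-connectivity would break
   apart.
2. **Spur pruning** (`prune_spurs()`): thinning converts small protrusions
   of the delineation into short false side branches. Terminal branches
   shorter than `min_branch` are removed iteratively until stable. The
   default is 2 mm — below the length of any plausible LSA, above the
   scale of tracing jitter. A skeleton without junctions is never pruned,
   so the main path always survives; if pruning ever consumes the path
   structure entirely (a sign the threshold is far too large), the
   function stops with an error rather than returning a fragment.
3. **Path extraction** (`extract_path()`): the centerline is the ordered
   pixel path realizing the longest geodesic distance between any two
   skeleton endpoints, found by pairwise shortest-path search over the
   skeleton graph (edges weighted by physical step length, anisotropic
   spacing respected per axis). Ties are broken deterministically toward
   the lexicographically smallest (row, col) start pixel. Disconnected
   skeletons are reported as errors carrying the component count; the
   batch driver (`measure_masks()`) logs and skips such masks instead of
   failing the run.

`mask_to_centerline()` chains these and then applies two conditioning
steps expressed in physical units so that results are comparable across
pixel grids: a moving-average smoothing of half-width 0.4 mm (pixel paths
zig-zag at the raster scale, which biases arc length upward; the window is
converted to pixels per mask) and arc-length-uniform resampling at 0.4 mm
steps (so angle-based metrics see the same effective sampling density
regardless of the underlying grid — 0.4 mm matches the finer axis of the
typical projected acquisition grid, 0.44 × 0.66 mm). Both knobs are
configurable; setting them to zero returns the raw pixel path.

3D volumes are handled the way the measurement was designed: a thin-slab
minIP (`min_intensity_projection()`) collapses the chosen slab to a 2D
image first, and measurement proceeds in 2D. Slab boundaries resolve to
whole voxel planes, rounding half toward the slab center. We deliberately
do not implement 3D curve skeletons; the slab and its center are
configuration inputs because slice selection was an expert decision in
the original workflow, not an algorithm.

## Per-vessel metrics

For a centerline with points $p_1,\dots,p_n$ (mm):

- **Vessel length** $L_A = \sum_i \lVert p_{i+1}-p_i \rVert$ — the actual
  path length from origin to terminal.
- **Chord** $L_C$ — the Euclidean distance between the endpoints.
- **Distance metric** $\mathrm{DM} = L_A / L_C \ge 1$ — conventional
  tortuosity; exactly 1 for a straight vessel. Closed curves (coincident
  endpoints) are reported as errors since DM is undefined there.
- **Vessel tortuosity index**
  $$\mathrm{VTI} = 0.1\,\mathrm{SD}_\theta \cdot N \cdot M \cdot \frac{L_A}{L_C}$$
  combining local and global shape features: $\mathrm{SD}_\theta$ is the
  sample standard deviation of the tangent angles along the centerline;
  $N$ counts the critical points where the slope of the tangent changes
  sign; $M$ is the mean arc-to-chord ratio over the segments between
  consecutive inflection points (curvature sign changes), endpoints
  included. VTI is zero exactly when $N = 0$ — a straight line is its
  theoretical minimum — and has no upper bound.

Design choices that the definition leaves open, and what we chose:

- **Frame.** Slopes measured against the raw image x-axis make $N$ (and
  hence VTI) depend on how the patient lay in the scanner. By default we
  rotate each centerline so its endpoint chord lies on the x-axis before
  computing $\theta$, $N$ and inflections; this makes DM and VTI exactly
  invariant under rigid motions. The raw image frame remains available
  via `frame = "image"` for strict replication of frame-dependent
  measurements.
- **Angle unit.** $\mathrm{SD}_\theta$ is in degrees by default
  (configurable); the choice rescales VTI globally and is recorded in the
  output column name.
- **Aggregating $M$.** The arc/chord ratio "between pairs of inflection
  points" needs an aggregator when there are several segments; we use the
  arithmetic mean, which keeps $M$ scale-free and makes $M = \mathrm{DM}$
  whenever the curve has a single curvature sign.
- **Tangent estimation.** Central differences over ±3 points (one-sided
  at the ends), unwrapped so consecutive angles never jump by more than
  180°. The window suppresses pixel-level jitter from manual tracing and
  is configurable.
- **Plateaus and jitter.** Zero-slope runs collapse to a single critical
  point candidate (otherwise rasterized horizontal stretches inflate
  $N$), the zero threshold is set relative to the curve's tangent scale
  (so an exactly straight line reads as all-zero slope rather than
  rounding noise), and slope-sign runs shorter than `min_run = 3` points
  are treated as rasterization jitter.

Per-subject summaries (`summarize_subject()`) report the LSA count plus
mean, median and sample SD (n − 1) of VL, DM and VTI; a single-vessel
subject reports SD 0 rather than NA so no subject drops out of group
statistics.

## The synthetic-data module

`generate_curve()` produces analytic centerlines — straight lines,
circular arcs, sinusoids, seeded random splines — sampled uniformly in
arc length (mimicking even pixel-wise delineation density), with ground
truth from closed forms where available and dense trapezoidal quadrature
(≥ 100× the sample density) otherwise. `rasterize_curve()` draws a curve
onto a pixel grid as a thin 8-connected Bresenham chain, optionally
thickened and decorated with seeded false spurs, emulating a manual
delineation. These two functions give every downstream stage an oracle:
the test suite checks, among others, that the full
rasterize → skeletonize → prune → extract → measure chain recovers
analytic DM and VL within 3% at pixel spacing of chord/50, over two
dozen curves spanning arcs, sinusoids and splines.

`generate_cohort()` simulates the kind of community-dwelling elderly
cohort the method targets: n = 125 by default; age from a truncated
normal (59.9 ± 7.1, range 50–82); balanced sex; independent Bernoulli
risk factors at prevalences 40.8% (hypertension), 15.2% (diabetes),
14.4% (hyperlipidemia) and 28.8% (smoking); artery diameters and
per-subject morphometry summaries with Gaussian marginals anchored to
the reference cohort (median LSA count 8, median vessel length
17.8 mm). Dependence between diameters and outcomes is induced by a
Gaussian copula whose latent correlations are chosen so the *Spearman*
targets hold ($r_{\text{latent}} = 2\sin(\pi r_s/6)$) — matching the
rank-based statistics used downstream. Risk-factor effects are injected
additively on the subject-level summaries, in units of each outcome's
SD, because that is the level at which the statistics operate. Infeasible
correlation targets (a latent matrix that is not positive definite) are
reported as errors, never silently clipped.

Default effect directions follow the reported epidemiology — smokers
shorter and straighter (−0.5 SD on median VL and DM, −0.55 on median
VTI), hypertension less tortuous (−0.4 SD on median VTI), MCA diameter
positively tied to LSA count (+0.278) and negatively to median VTI
(−0.252), PCA diameter positively tied to length and tortuosity. The
*magnitudes* for risk factors are package defaults chosen once to be
moderate, plausible effects; the source analyses report only directions
and p-values, so no published magnitudes exist to copy.

What the generator does **not** emulate: MRI physics and contrast, 3D
branching vessel trees, inter-correlation among a subject's summary
statistics (mean/median/SD of an outcome are drawn as separate copula
marginals apart from the configured structure — real summaries would be
strongly dependent), spatially structured delineation error, and any
dependence of CSVD markers on morphometry. Passing tests therefore
demonstrate that the measurement chain and statistics behave correctly
under controlled conditions, not that real LSA data will show any
particular effect.

## Cohort statistics

- `adjusted_group_compare()` — ANCOVA-style comparison: the outcome is
  modeled on the binary group plus covariates (age, sex, ICV by default)
  with a linear model, and the group term's partial F test is reported
  with the adjusted group-mean difference. With no covariates this is
  exactly one-way ANOVA. We chose ANCOVA over ANOVA-on-residuals; with
  the same covariate set the two differ only in degrees of freedom, and
  ANCOVA is the standard formulation.
- `rank_correlation()` — partial Spearman: both variables *and* the
  covariates are rank-transformed (midranks for ties), the covariates are
  regressed out of each rank vector, and the Pearson correlation of the
  residuals is reported with a t-approximate p (df = n − 2 − k). Ranking
  the covariates matters: partialing raw covariates out of ranks leaves
  nonlinear leakage that shows up as spurious partial association.
  Without covariates the statistic is exactly classical Spearman.
- `chi_square()` — Pearson 2×2 test without continuity correction
  (configurable).
- `bonferroni()` — p × m capped at 1. `run_full_analysis()` applies it
  within each of two families matching how the comparisons group: the
  risk-factor × {median DM, median VTI, median VL, count} ANCOVA grid
  (m = 16) and the diameter × {count, mean/median DM, VTI, VL} Spearman
  grid (m = 35). Family membership is recorded with every result.
- `icc_consistency()` — two-way mixed, absolute-agreement, single-rater
  ICC, the appropriate index for intra-observer repeat measurements;
  computed from the two-way ANOVA mean squares.

Missing data are handled by listwise deletion per comparison, with the n
actually used reported in every result row.

## Numerical choices and degenerate inputs

- Pixel-to-mm conversion uses pixel centers and per-axis spacing; nothing
  assumes isotropy.
- Geodesic ties in path extraction break toward the lexicographically
  smallest start pixel, so repeated runs are bit-identical.
- A straight line's slope sequence is recognized by a tolerance relative
  to the tangent magnitude (10⁻⁸), not an absolute epsilon.
- Closed centerlines (DM undefined), empty masks, disconnected skeletons,
  constant outcomes, degenerate 2×2 margins and zero-variance ICC inputs
  all raise informative errors; the batch drivers skip-and-log rather
  than abort where a single bad vessel should not kill a cohort run.
- All simulation is seeded through a single integer per run; manifests
  record the seed and a hash of the configuration.

## Validation scale

The test suite exercises: 24-curve raster round-trips at spacing
chord/50 (3% tolerance on DM and VL); closed-form spot checks
(semicircle DM = π/2 to 0.5%, sin(x) on [0, 2π] DM ≈ 1.216 to 1% with
N = 2); rigid-motion invariance (10⁻⁶ relative on analytic centerlines;
1% after rasterization at chord/200, where digitization noise is small
enough for the five-factor VTI product to stabilize); a five-amplitude
sinusoid monotonicity ladder; type-I calibration of the adjusted group
comparison over 1,000 null cohorts of n = 125 (3–7% at α = 0.05); and
power ≥ 80% with correct sign for a −0.6 SD smoking effect on median VL
over 200 cohorts. These sizes keep the full suite under a minute on one
core while leaving the binomial error of the calibration runs well below
the tested margins.

## Known limitations

- Measurement is 2D (projection-based), matching the clinical workflow;
  vessels coursing perpendicular to the projection plane are
  foreshortened, exactly as in the original measurement.
- Thinning erodes the tips of thick delineations by up to about half the
  stroke width, so very short, very thick masks lose proportionally more
  length.
- The VTI scale depends on conventions (angle unit, frame, tangent
  window); comparisons across studies require matching configurations,
  which is why every knob is explicit in `run_config()` and recorded in
  output manifests.
- The paper-scale cohort findings (specific correlations and p-values)
  are not reproducible from this package alone: the underlying cohort
  data are not public. The simulator reproduces the *marginals* and
  *effect directions*; the statistical guarantees shipped here are
  calibration and power properties, verified by simulation.
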