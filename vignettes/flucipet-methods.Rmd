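---
title: "Semiquantitative dynamic fluciclovine PET analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquantitative dynamic fluciclovine PET analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucipet)
```

## The problem

Amino-acid PET of glioma exploits the low amino-acid transport of normal
brain: tumors light up against a quiet background, and the contrast grows
with grade. For dynamic fluciclovine imaging the analysis chain is
semiquantitative: place a spherical ROI over the tumor, mirror its
location across the midsagittal plane to obtain a contralateral
normal-brain background sphere, segment "metabolically active tumor" as
the voxels above a multiple (1.3x, 1.6x, 1.9x) of the background SUVmean,
and track SUVmax, SUVmean and the tumor-to-background ratios

$$\mathrm{TB}_{max} = \frac{\mathrm{SUV}_{max}^{tumor}}{\mathrm{SUV}_{mean}^{bkg}},
\qquad
\mathrm{TB}_{mean,k} = \frac{\mathrm{SUV}_{mean}^{tumor \ge k \cdot bkg}}{\mathrm{SUV}_{mean}^{bkg}}$$

across a 65-minute dynamic acquisition (15 frames: 6 x 30 s, 4 x 180 s,
5 x 600 s). Time-activity curves (TACs) flatten from roughly 30 min
post-injection, consistent with an influx/efflux equilibrium, so grade
discrimination pools the 30/40/50/60-min frames, derives ROC cutoffs for
high-grade (WHO III/IV) versus low-grade (WHO II) tumors, screens the
four candidate metrics with a lasso-logistic model, and correlates uptake
with the Ki-67 proliferation index.

Because per-lesion SUV values of a clinical cohort are not publicly
available, every stage of this package is driven by a synthetic 4D
phantom generator with full ground truth. The package is therefore a
*method* implementation validated by construction, not a re-analysis of
patient data; the packaged cohort table (`cohort_table1.tsv`) carries only
demographics, histology, grade and Ki-67, and phantom-derived tables are
always labeled synthetic.

## The tissue kinetics model

Each phantom tissue follows

$$S(t) = S_{eq}\, g(t) + m \max(0,\, t - t_d), \qquad
g(t) = \frac{1}{T_{inf}} \int_0^{\min(t,\,T_{inf})}
\big(1 - e^{-k (t-u)}\big)\, du,$$

the response of a first-order uptake compartment to a constant-rate
infusion of duration $T_{inf}$ (default 4 min, matching a slow pump
administration used to broaden the input function), with the bolus limit
$g(t) = 1 - e^{-kt}$ at $T_{inf} = 0$. $g$ rises monotonically to 1, so
$S_{eq}$ is the equilibrium SUV; the optional drift term ($m$ SUV/min
after $t_d$) creates controlled departures from equilibrium for power
studies. The closed form

$$g(t) = \frac{1}{T_{inf}}\left[\tau - \frac{e^{-k(t-\tau)} - e^{-kt}}{k}\right],
\qquad \tau = \min(t, T_{inf}),$$

is evaluated directly (no quadrature in the rendering hot path) and is
overflow-safe for large $k$. This is an *emulation* of the empirically
observed rise-then-plateau TAC shape, not a pharmacokinetic model of
fluciclovine transport; images are assumed decay-corrected, so no decay
term appears.

A recorded frame value is the *time-average* of $S(t)$ over the frame
interval — the behavior of histogrammed list-mode data — computed by
8-point Gauss–Legendre quadrature on panels split at the model's kink
points (end of infusion, drift onset), which is exact to near machine
precision for these exponentials. Tests compare it against adaptive
numerical integration of the TAC.

## Phantom design decisions

- **SUV scale.** Phantoms are generated directly in SUV units; injected
  dose and body weight are not simulated. All downstream metrics are
  ratios or maxima of SUVs, so nothing is lost.
- **Resolution.** The default PSF is an isotropic Gaussian of 4.6 mm
  FWHM — a typical *final* reconstructed resolution for a high-resolution
  brain tomograph. Acquisition protocols sometimes quote much wider
  post-reconstruction smoothing kernels that cannot be reconciled with
  such a final resolution; `psf_fwhm_mm` is fully configurable, and the
  default favors the final-resolution reading.
- **Blur implementation.** Separable per-frame 3D convolution with
  reflective (half-sample symmetric) boundaries. Rows of the 1D operator
  sum to one, so constants are eigenfunctions and interior-supported
  signal totals are conserved (tested to 0.1%).
- **Noise.** Additive i.i.d. Gaussian in SUV, seedable and reproducible.
  Post-reconstruction, post-smoothing PET images are approximately
  Gaussian; Poisson projection noise and reconstruction (OP-OSEM,
  attenuation/scatter/randoms) are out of scope.
- **Geometry.** World coordinates in mm; a voxel belongs to a region iff
  its center is inside (center-in convention), applied uniformly to
  spheres and ellipsoids. Default grid 64 x 64 x 48 at 2.4-mm isotropic
  voxels: the 4.6-mm PSF is sampled at better than Nyquist while a
  whole-cohort phantom stays small enough to render in seconds.
- **Cohort phantom layout.** Lesions are placed on interior rings of one
  hemisphere only, so each lesion's contralateral mirror lands in normal
  brain; a venous sphere sits at the ring center. Default tissue levels:
  normal brain plateau 1.3 SUV ($k = 0.25$/min, essentially at
  equilibrium by 30 min), venous 1.25 SUV (deliberately close to brain —
  venous and parenchymal uptake do not differ appreciably for this
  tracer), HGG lesion plateaus $\mathcal{N}(4.5, 0.7^2)$ and LGG
  $\mathcal{N}(2.7, 0.25^2)$ SUV with $k = 0.18$/min, i.e. true TB ratios
  near 3.5 (HGG) and 2.1 (LGG) bracketing clinically reported TBmean
  cutoffs; noise SD 0.1 SUV (roughly 8% of background). A synthetic
  Ki-67 index is drawn as an increasing noisy function of the true TB
  ratio.
- **Metric frames.** Background-normalized ratios are undefined while
  tissue activity is still near zero during the infusion, so the pipeline
  measures metrics from the first post-infusion frame (mid-time 4.5 min)
  onward — also the point from which clinical TAC displays conventionally
  start. All frames remain in the image container.

## ROI and metric conventions

- The background sphere is 15 mm in **diameter** (the conventional size
  quoted for PET background spheres), fixed once per lesion and reused
  across all frames; each frame's ratios use that frame's own background
  mean.
- Threshold comparison is `>=` — a *minimum* threshold includes boundary
  voxels.
- SUVmax is the single hottest voxel in the search region (after
  exclusions); SUVpeak is an explicit non-goal.
- An empty threshold mask yields missing SUVmean/TBmean (never zero) with
  zero segmented volume, so attrition and non-segmentable frames are
  explicit in downstream statistics.
- The tumor search region stands in for a FLAIR-hyperintensity-based ROI;
  no MRI is simulated, and the phantom supplies masks or sphere centers
  directly. The phantom's normal brain is a single tissue class, so the
  gray/white composition of a clinical background sphere collapses here.

## Equilibrium (plateau) analysis

Observations at frame mid-times $\ge$ 30 min enter an unbalanced two-way
ANOVA (factors: time point and tissue group) with type-II sums of
squares — the appropriate choice when imbalance comes from attrition
rather than design — followed by Tukey HSD comparisons between time
points within each group. A group is *plateaued* when no within-group
time pair is significant at $\alpha = 0.05$. Borderline single-pair
differences (e.g., a 30-vs-50-min contrast significant while all others
are not) are a recognized ambiguity of this criterion, so the per-pair
adjusted p-values are always returned and callers can apply their own
reading. Groups represented by a single ROI (such as one venous
confluence) get `NA` — comparisons unavailable — rather than a silent
pass. Missing late frames are never imputed; group TAC averages carry a
per-point $n$.

Calibration (tested): with drift-free kinetics and exchangeable frame
noise the plateau flag rejects in about 5% of 500 replicates at
$\alpha = 0.05$; rejection power grows with the drift slope and reaches
1 for strong drift. When a shared per-lesion random level is added, the
pooled-residual Tukey test becomes conservative (the lesion variance
inflates the error term while time contrasts cancel it); the calibration
claim applies to the exchangeable case.

## Grade discrimination

- **Positive class** is HGG; sensitivity is the HGG detection rate.
- Observations pooled across equilibrium time points are treated as
  independent for ROC construction (matching clinical pooled-denominator
  practice); a per-lesion alternative is a one-liner
  (`aggregate(value ~ lesion_id + grade_class, obs, mean)`) upstream of
  `roc_analysis()`.
- Candidate thresholds are midpoints between consecutive sorted unique
  values plus $\pm\infty$ sentinels; AUC is trapezoidal and provably
  equals Mann–Whitney concordance with ties counted 1/2 (tested against a
  brute-force oracle to 1e-12, plus invariance under strictly increasing
  transforms).
- The operating point maximizes **Youden's J**, breaking ties toward
  higher sensitivity. A pure "sensitivity first, then specificity" rule
  is degenerate — it always selects the minimum threshold — so Youden is
  the operative criterion and the tie-break preserves the
  sensitivity-priority intent.
- WHO III lesions count as HGG for ROC and TAC grouping but are excluded
  from the II-vs-IV Welch t-tests, which compare only the unambiguous
  grade strata. `welch_t()` adopts the convention $p = 1$ for two
  zero-variance samples with equal means (where `t.test()` errors).
- Ki-67 `"<1"` tokens parse to 0.5 (interval midpoint; configurable) and
  `"N/A"` rows are dropped from correlations. Correlation p-values across
  metrics are reported raw, without multiplicity correction.
- Lasso-logistic screening standardizes predictors, records the order in
  which each metric enters the regularization path, and flags relevance
  as a nonzero coefficient at the cross-validated penalty under the 1-SE
  rule with seeded folds. Support recovery is verified by simulation
  (two informative + two noise metrics, $n = 400$, recovered in
  $\ge 90\%$ of 100 replicates; all-noise draws stay empty).

## What passing tests do and do not show

The phantom reproduces the *structure* of the clinical analysis —
schedule, plateau kinetics, background normalization, threshold nesting,
grade separation, attrition bookkeeping — with exact ground truth. It
does not emulate tumor heterogeneity (lesions are uniform spheres),
infiltrative margins, reconstruction artifacts, motion, blood-pool
spillover into adjacent structures, or the gray/white background mix.
Numeric outputs of the pipeline on phantoms (AUCs, cutoffs, correlation
coefficients) therefore validate the machinery and its calibration, not
clinical performance; published clinical cutoffs depend on per-lesion
values that only a real cohort can supply.

## Numerical choices and degenerate inputs

- Frame averaging: Gauss–Legendre, 8 nodes per smooth panel, panels split
  at kinetic kinks.
- Blur: operator rows renormalized after truncation at $4\sigma$;
  `fwhm = 0` is an exact identity.
- ROC ties: midpoint thresholds make `>` vs `>=` classification
  equivalent; tied Youden maxima resolve toward higher sensitivity, then
  the lower threshold.
- Perfect-fit ANOVA (all values identical): pairwise p-values are set to
  1 for zero differences and 0 otherwise instead of propagating NaN from
  a zero residual.
- Zero-variance inputs: correlation returns a flagged degenerate result;
  constant lasso predictors are excluded with a warning; Welch follows
  the $p \in \{0, 1\}$ convention above.
- All randomness (phantom noise, CV folds, simulations) flows through
  explicit integer seeds; the caller's RNG state is restored.

## Problem sizes used in the shipped checks

Simulation-based checks run at: 100 random fields for segmentation
nesting; 50 samples for the AUC/concordance oracle plus one 400-point
null draw; 200 replicates for cutoff recovery and 500 for Ki-67
correlation recovery at $n = 13$; 500 null and 160 alternative replicates
for plateau calibration; 100 + 50 replicates at $n = 400$ for lasso
support recovery. The acceptance pipeline renders an 18-lesion phantom on
the default 64 x 64 x 48 grid. These sizes were chosen so Monte-Carlo
error is small relative to each asserted margin.

## Limitations

Single-tissue normal brain; uniform spherical lesions; additive Gaussian
noise only; no reconstruction or MRI co-registration; no partial-volume
correction (recovered TBmean converges to truth only as the PSF width
goes to zero, which the tests exercise); no survival, pseudo-progression,
or IDH-stratified analyses.
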