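# flucipet

Semiquantitative analysis of **dynamic fluciclovine (18F) brain PET** for
glioma grading, driven by a synthetic 4D phantom generator with full
ground truth.

## The problem

Distinguishing high-grade (WHO III/IV) from low-grade (WHO II) glioma
non-invasively is hard: MRI enhancement is neither sensitive nor specific
for grade. Amino-acid PET tracers such as fluciclovine produce
high-contrast tumor images because normal brain takes up little tracer,
and the contrast carries grade information. The standard semiquantitative
chain is:

1. Acquire a dynamic scan (15 frames: 6 × 30 s, 4 × 180 s, 5 × 600 s,
   ending at 65 min) during and after a 4-min infusion.
2. Place a spherical search ROI over the tumor and a 15-mm background
   sphere over the **contralateral** normal brain (the tumor location
   mirrored across the midsagittal plane).
3. Segment *metabolically active tumor* as voxels ≥ k × background
   SUVmean for k ∈ {1.3, 1.6, 1.9}, and record per frame
   SUVmax, SUVmean, and the tumor-to-background ratios
   TBmax = SUVmax / SUVmean(bkg) and
   TBmean_k = SUVmean(≥ k·bkg) / SUVmean(bkg).
4. Time-activity curves flatten from ≈ 30 min (influx/efflux
   equilibrium, testable by unbalanced two-way ANOVA + Tukey HSD), so
   observations from the 30/40/50/60-min frames are pooled for
   ROC analysis (HGG = positive class, Youden-optimal cutoff),
   Welch t-tests of WHO II vs IV, lasso-logistic screening of the four
   candidate metrics, and Pearson correlation with the Ki-67
   proliferation index.

Per-lesion clinical SUVs are not publicly available, so the package
ships a seedable phantom module (tissue kinetics → frame-averaged 4D
volume → Gaussian PSF → additive noise, with exact ground truth) and
exercises every stage on it. The packaged `cohort_table1.tsv` holds only
demographics/histology/grade/Ki-67; all phantom-derived tables are
explicitly synthetic. See `vignettes/flucipet-methods.Rmd` for the model
and every design decision.

Intended users: PET methodologists and image-analysis developers who
need a tested, reproducible reference implementation of
background-normalized threshold segmentation and TAC-equilibrium ROC
analysis.

## Worked example

```r
library(flucipet)

# 18-lesion phantom cohort (12 HGG, 6 LGG) with grade-specific kinetics
b <- build_cohort_phantom(n_hgg = 12, n_lgg = 6, seed = 42)
r <- render_phantom(b$spec)
r$image
#> Dynamic image: 64 x 64 x 48 voxels x 15 frames, 2.4 mm voxels

# search ROI around each lesion; background = contralateral mirror sphere
geom <- image_geometry(r$image)
mid_x <- b$spec$brain$center[1]
searches <- lapply(r$truth$lesion_centers, function(ctr)
  sphere_mask(sphere_roi(ctr, 2 * (r$truth$lesion_radii[1] + 4)), geom))
backgrounds <- lapply(r$truth$lesion_centers, function(ctr)
  sphere_roi(mirror_contralateral(ctr, mid_x), 15))
post <- which(r$image$schedule$mid_min >= 4.5)  # post-infusion frames
metrics <- compute_uptake_metrics(r$image, searches, backgrounds, frames = post)

# pooled 30-60 min observations -> ROC cutoff for HGG vs LGG
obs <- pool_equilibrium(metrics, b$cohort, "tb_mean_1.3")
roc_analysis(obs)
#> ROC: AUC 1.000 | cutoff > 1.79: sensitivity 100.0%, specificity 100.0% (n+ = 48, n- = 24)

# uptake vs (synthetic) Ki-67 at 30 min
at30 <- metrics[metrics$time_min == 30, ]
ki <- b$cohort$ki67_value[match(at30$lesion_id, b$cohort$lesion_id)]
ki67_correlation(at30$tb_mean_1.3, ki)
#> Correlation: R = 0.911, p = 1.52e-07 (n = 18)
```

The ROC line reads: pooling the four equilibrium frames of all 18
lesions (48 HGG and 24 LGG observations), a TBmean(1.3) cutoff of 1.79
separates the generated grade classes perfectly — expected here, because
the phantom's grade separation is strong by construction. The
correlation line shows the recovered association between TBmean(1.3) and
the synthetic Ki-67 index across the 18 lesions.

`run_pipeline(demo_config(seed = 1), "out/")` runs the same chain end to
end and writes `metrics.csv`, `roc.csv`, `tac_report.json`,
`correlation.json`, `synthetic_cohort.tsv` and `summary.txt`; reruns
with the same seed are byte-identical.

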