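# psmdkit

Quantitative assessment of cerebral small vessel disease (SVD) from
template-space MRI: the **peak width of skeletonized mean diffusivity
(PSMD)**, threshold-based white matter hyperintensity (WMH) quantification,
the four-marker SVD rating schema with the 0–4 total burden score, and the
statistical machinery needed to relate these markers to one another and to
cognition.

## Who this is for

Neuroimaging researchers who work with diffusion-MRI markers of
cerebrovascular damage. PSMD is attractive because it is fully automated and
cheap to compute at scale, but validating an analysis chain around it
requires data with known ground truth. `psmdkit` therefore ships a synthetic
phantom and cohort generator that plants known peak widths, lesions and
marker–cognition structure, so every stage of the chain can be verified
end to end without access to clinical scans.

## The statistic at the core

Given a mean-diffusivity volume MD, a fractional-anisotropy volume FA and a
binary white-matter skeleton mask on a common template grid, the skeleton
value set is

S = { MD(v) : skeleton(v) = 1 and FA(v) ≥ 0.2 },

and PSMD is the width of the central 90% of its histogram:

PSMD = P95(S) − P5(S),

with percentiles computed by linear interpolation between order statistics
at rank 1 + (n−1)q. The FA ≥ 0.2 mask removes CSF-contaminated voxels;
restricting S by a lobar atlas yields regional PSMD. For a Gaussian value
distribution PSMD = 2·z₀.₉₅·σ ≈ 3.2898 σ, which is what the phantom
generator inverts to plant a target peak width.

Around the statistic the package implements the full study battery:

* WMH segmentation at intensities strictly above 1.40 × the modal in-brain
  intensity, periventricular/deep partition by distance to the ventricles,
  lobar partition by atlas, TIV normalization and square-root transform;
* the four semi-quantitative SVD scales (Fazekas, EPVS grades, microbleed
  and lacune counts with the 3–15 mm size rule) and the 0–4 burden score;
* Huber robust regression (IRLS, MAD scale), percentage-bend robust
  correlation, Fisher r-to-z contrasts, full-enumeration dominance analysis,
  Johnson relative weights, ROC/AUC with DeLong comparison of correlated
  curves, and Holm–Bonferroni correction.

## Worked example

```r
library(psmdkit)

# a 64^3 phantom with a planted peak width and two planted lesions
ph <- generate_phantom(phantom_spec(
  target_psmd = 5.51e-4, seed = 1,
  lesion_blobs = list(
    list(center = c(32, 32, 40), radius_mm = 8, multiplier = 1.6),
    list(center = c(20, 32, 32), radius_mm = 5, multiplier = 1.8))))

compute_psmd(ph$bundle)
#> PSMD (peak width of skeletonized mean diffusivity)
#>   psmd     : 0.000546232 mm^2/s  (p95 0.0010432 - p5 0.000496966)
#>   voxels   : 12230
#>   MD mean  : 0.000769005 (sd 0.000165727)
#>   FA mean  : 0.4896 (sd 0.0797)

seg <- segment_wmh(ph$flair, ph$brain_mask, k = 1.40, ph$voxel_size)
seg <- partition_wmh(seg, ph$ventricle_mask, ph$atlas, pv_distance_mm = 10)
seg
#> WMH threshold segmentation
#>   modal intensity : 99.4491 (threshold 139.229 = 1.40 x mode)
#>   total volume    : 2704.0 mm^3 (338 voxels)
#>   PVH / DWMH      : 2120.0 / 584.0 mm^3
```

The recovered peak width is within 1% of the planted 5.51e-4 mm²/s (the
residual error is percentile sampling noise at 12k voxels), and the 338
recovered lesion voxels are exactly the planted set: the blob 2 mm from the
ventricles lands in PVH, the far one in DWMH.

A complete synthetic study — robust association battery (Models 1 and 2),
importance tables, regional correlation matrix and ROC comparison — runs
from one call and writes its tables as CSV:

```r
res <- run_study(study_config(), out_dir = "study_out", seed = 7)
subset(res$roc, score %in% c("psmd", "wmh_sqrt"),
       c(score, auc, ci_lo, ci_hi, p_vs_psmd))
#>      score       auc     ci_lo     ci_hi p_vs_psmd
#> 1     psmd 0.7061490 0.6217141 0.7905839  1.000000
#> 2 wmh_sqrt 0.7210959 0.6318174 0.8103744  0.787355
```

A thin CLI wrapping the same functions is installed at `exec/psmdkit`
(subcommands `simulate`, `psmd`, `wmh`, `run-study`).

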