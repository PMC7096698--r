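---
title: "Methods: peak width of skeletonized mean diffusivity and the SVD analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak width of skeletonized mean diffusivity and the SVD analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmdkit)
```

## The statistic and its assumptions

PSMD summarizes diffuse white-matter damage as the width of the central 90%
of the mean-diffusivity histogram on the white-matter skeleton:

$$\mathrm{PSMD} = P_{95}(S) - P_{5}(S), \qquad
S = \{\, \mathrm{MD}(v) : \mathrm{skeleton}(v)=1 \wedge \mathrm{FA}(v)\ge 0.2 \,\}.$$

The statistic depends only on the masked value multiset, not on its spatial
arrangement, which is why `psmdkit` consumes template-space volumes and
treats registration and skeleton projection as upstream concerns. The
FA ≥ 0.2 mask exists to exclude CSF-contaminated voxels, whose high
diffusivity would otherwise inflate the upper tail; the percentile spread
(rather than, say, the SD) makes the measure resistant to the remaining
tail mass. Under a Gaussian value distribution
$\mathrm{PSMD} = 2\,z_{0.95}\,\sigma \approx 3.2898\,\sigma$; under
Uniform$(a,b)$ it is $0.9\,(b-a)$. Both closed forms are used as oracles in
the test suite.

Numerical conventions, fixed because published descriptions leave them open:

* **Percentile rule** — linear interpolation between order statistics at
  rank $1+(n-1)q$ (R's `quantile` type 7, the convention used by the
  dominant scientific numerics libraries).
* **FA threshold** — applied inclusively (FA = 0.2 is kept), matching
  tract-based skeleton practice; the boundary is covered by a test.
* **Double masking** — subject-skeleton and template-FA masks compose into
  one boolean conjunction here, since inputs are already co-registered.
* **Skeleton SD** — the $n-1$ denominator (sample statistic over skeleton
  voxels).
* **Degenerate inputs** — non-finite MD voxels are excluded with a reported
  count; negative MD voxels are retained with a warning, preserving the
  masked multiset as defined while surfacing upstream problems; an empty
  post-masking multiset is an error, not a zero.
* **Regional analysis** — regions with fewer than `min_voxels` (default
  100) surviving voxels are reported missing with their observed count: a
  peak width over a handful of order statistics is noise.

## WMH quantification

Lesions are in-mask voxels with intensity **strictly greater** than
$k \times$ the modal in-brain intensity, $k = 1.40$ by default ("more than
1.40 times" reads as a strict inequality; a voxel exactly at the threshold
is excluded, and a test pins this). The mode is estimated by a fixed-bin
histogram (256 bins spanning the in-mask range, ties broken toward the
lower bin, bin center returned) — a deterministic, documented estimator is
a precondition for reproducible segmentation. The threshold multiplier is
exposed as a free parameter: 1.40 was presumably tuned for a particular
scanner's FLAIR contrast and no transferability is claimed.

The periventricular/deep split uses a Euclidean distance-to-ventricle rule
(PVH iff the voxel center lies within 10 mm of a ventricle voxel,
inclusive, configurable): the literature names the split but not the
geometric rule, and the distance convention composes cleanly with the
phantom's analytic geometry. Lobar volumes accumulate by atlas label;
lesion voxels outside the atlas are reported under `unassigned` rather than
silently dropped. Expert manual correction of segmentations is represented
as a voxelwise override mask (`apply_edit_mask()`), logged, with partition
fields reset — the review step has no algorithmic content to model.
Volumes are normalized as percent of total intracranial volume and
square-root transformed, the standard variance-stabilizing choice for
right-skewed lesion volumes.

## Rating schemas and the burden score

The four marker scales are encoded as validated schemas: Fazekas PVH/DWMH
grades 0–3, EPVS grades 0–4 in centrum semiovale and basal ganglia with a
dichotomous midbrain rating, and microbleed/lacune counts by deep/lobar
location. Lacune candidates pass an inclusive 3–15 mm diameter band (below:
likely perivascular spaces; above: likely non-SVD lesions). The burden
score awards one point per marker class present — WMH (PVH grade 3 and/or
DWMH ≥ 2), basal-ganglia EPVS ≥ grade 2 (i.e. more than 10, the "moderate
to severe" cut), any lacune, any microbleed. A missing modality (e.g. no
susceptibility-weighted scan) makes the affected counts and the score
missing, never zero. "Possible" microbleeds are retained only as an audit
field and never analyzed.

## The statistical stack

* **Robust regression** (`robust_fit`) — Huber M-estimation by IRLS:
  tuning constant 1.345 (95% efficiency at the normal), scale re-estimated
  each iteration as $\mathrm{median}|r|/0.6745$, convergence when the
  largest coefficient change falls below 1e-8 (cap 50 iterations,
  non-convergence flagged rather than raised). Wald t statistics use the
  Huber-corrected covariance and a $t_{n-p}$ reference — a documented
  approximation; the test suite verifies 3–7% empirical size at n = 100.
  As the tuning constant grows the fit reduces to OLS, which anchors the
  estimator's identity test.
* **Robust correlation** — the percentage-bend estimator with bend
  constant 0.2, p-values from the $t_{n-2}$ approximation. The estimator
  is stated explicitly because "robust correlation" names a family, not a
  method.
* **Fisher r-to-z** — the independent-samples contrast
  $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3)+1/(n_2-3)}$.
  Applying it to two correlations sharing a sample (as the regional
  contrasts do) ignores their dependence; a dependent-correlations test
  would need the unobserved cross-correlation, so the independent form is
  used and labeled as such.
* **Dominance analysis** — general dominance weights by full subset
  enumeration, capped at 15 predictors ($2^p$ least-squares fits); the
  weights sum to the full-model $R^2$ exactly.
* **Relative weights** — Johnson's orthogonal-counterpart decomposition via
  the symmetric square root of the predictor correlation matrix. Percent
  contribution columns are normalized relative weights. Under an exactly
  orthogonal (centered) design both decompositions collapse to squared
  zero-order correlations — a closed-form oracle in the tests.
* **ROC/DeLong** — AUC by midranks (ties count 1/2) and DeLong
  placement-value covariance for correlated curves; a score contrasted
  with itself is defined to give p = 1, and a zero-variance difference is
  flagged rather than divided by.
* **Holm–Bonferroni** — step-down adjustment via `stats::p.adjust`;
  rejection uses a strict comparison with α. Families are corrected per
  results block (the marker battery within each model; the regional matrix
  as its own family).

## What the generators emulate — and what they do not

`generate_phantom()` builds co-registered volumes in which every downstream
quantity is planted: skeleton MD is Gaussian with
$\sigma = \mathrm{PSMD}^\ast/3.2898$ truncated at zero; a configurable
contaminant fraction of skeleton voxels carries FA < 0.2 with CSF-like MD,
so FA masking is load-bearing rather than decorative; the FLAIR background
is a clipped Gaussian (mode preserved, support bounded at 1.3 × mode) so
that planted spherical lesions at ≥ 1.5 × mode — rasterized by
center-of-voxel inclusion, which gives analytic volumes — are recoverable
voxel-exactly; ventricles are a central ellipsoid and the lobar atlas an
octant partition of the brain mask. The skeleton itself is a union of
axis-aligned one-voxel sheets through the brain interior: since PSMD
depends only on the masked multiset, realistic skeleton geometry would add
cost without adding test power. Scanner physics, registration error,
motion-corrupted diffusion volumes and bias fields are explicitly out of
scope, so passing phantom tests demonstrates correctness of the masking,
histogram and segmentation arithmetic — not robustness to acquisition
artifacts.

`generate_cohort()` draws subject tables from a latent-severity model: one
latent severity per subject (shifted additively by diagnostic group) loads
with `marker_correlation` (default 0.6, stipulated — marker
intercorrelations are not published for the reference cohort) on log-normal
WMH volume, negative-binomial microbleed and lacune counts (dispersions
0.25/0.3, chosen for the heavy overdispersion seen in clinic samples, e.g.
mean 1.44 vs SD 6.3 for microbleeds), thresholded-latent EPVS grades and
Fazekas grades. PSMD is linear in transformed WMH, microbleed count and
head motion; ACE-R is linear in PSMD and GM volume with additive group
shifts, truncated to [0, 100]; MMSE derives from ACE-R. Head motion is a
positive log-normal scalar correlated 0.2 with severity, reproducing the
confound the regression models adjust for. Missing modalities are planted
at the observed study rates (3/145 for SWI, 16/145 for volumetric FLAIR).
Default magnitudes were chosen once to match the published marginal moments
of a 145-subject memory-clinic cohort (PSMD 5.51e-4 (1.03e-4) mm²/s,
sqrt-normalized WMH 0.69 (0.71), GM 39.0 (2.9) %TIV, ACE-R 79.4 (15.0),
group sizes 33/20/16/23/26/6/21) and are not adjusted thereafter.

Named scenarios (`cohort_scenario()`) express the generative conditions the
validation suite probes: `"wmh_driver"` and `"psmd_driver"` make the
respective effect large relative to its residual SD, `"motion_driver"`
routes all PSMD signal through the confounder, and `"null"` zeroes every
slope for calibration checks. Recovery of the planted orderings on these
scenarios shows internal consistency of the chain; it does not certify the
orderings in any real cohort, where group structure leaks into cognition
through paths other than PSMD.

## Design choices where the design was genuinely open

* The study driver operates on the simulated cohort table; per-subject
  volume processing is exposed and tested via `extract_subject_metrics()`
  rather than re-deriving 145 phantoms per study run, since the table
  carries the same fields with planted truth.
* Diagnosis enters Model 2 as a categorical fixed effect with the healthy
  group as reference. Listwise deletion is applied per model with the
  per-model n reported in every output row.
* The WMH point of the burden score is computed from the Fazekas grades
  only (the quoted definition), even when volumetric WMH exists.
* ROC orientations are declared per score (larger = more impaired for
  pathology markers; inverted for volumes and FA) instead of inferred from
  the data, and recorded in the output.
* The package is organized as a toolbox of composable operations rather
  than around a single fitting function: the subject of the analysis is a
  chain (generation → masking → histogram → segmentation → batteries), and
  no one estimator owns the interface. `robust_fit()` still returns a
  classed object with `print`/`summary`/`coef` methods.

## Problem sizes and tolerances used in validation

Analytic PSMD laws are checked at 1e5 (uniform, 2%) and 1e6 (Gaussian, 1%)
draws; the sort-and-interpolate oracle at ≤ 1000 voxels to 1e-12 relative
error. Phantom calibration uses ≥ 1e5 skeleton voxels (2% tolerance, the
percentile sampling noise at that size being ≈ 0.3%). Dominance weights are
compared with brute-force enumeration at p = 3 and 4 to 1e-10. DeLong
variance is compared with a 2000-replicate stratified bootstrap at 50 per
class (15%). Calibration simulations use 500 null cohorts of n = 100
(size 5% ± 2%) and 200 replicate cohorts of n = 145 for the
ordering-recovery checks (≥ 90% threshold). These sizes keep the whole
suite in the tens of seconds while leaving comfortable Monte-Carlo margins.

## Known limitations

The phantom validates arithmetic, not acquisition robustness; the cohort
model is linear-Gaussian in its structural equations and cannot represent,
e.g., floor effects in cognitive tests other than by truncation; the
Fisher regional contrasts ignore within-sample dependence; Huber p-values
rely on an asymptotic reference distribution; and the printed coefficients
of any particular clinical cohort are not reproducible from synthetic data
— the package's claims are about the correctness and calibration of the
chain, verified against planted ground truth.
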