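---
title: "Methods: streamline bundle clustering and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streamline bundle clustering and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlekit)
```

bundlekit implements the analysis pipeline of a population DTI study of
white-matter microstructure: per-voxel diffusion tensor indices, automated
multi-subject segmentation of streamlines into named tracts, per-subject
tract summaries (mean FA, tract volume), intracranial-volume (ICV) matched
subgroup construction, and a regression/permutation statistical layer
relating the DTI indices to ICV, sex and age. Because cohort MRI data of
this kind cannot be shared, the package pairs every stage with a synthetic
generator so the whole pipeline is exercisable and testable end to end.
This vignette records the models, the tunable parameters, and the design
choices made where the methodology was genuinely open.

## The forward cohort model

`generate_cohort()` runs the analysis model forward. Each subject has a sex,
an age drawn uniformly on 50–66 years (the study's narrow recruitment
window; the exact empirical age distribution within such a window is not
critical and a uniform draw is the least committal choice), and an ICV drawn
from sex-specific normals — men 1667.9 ± 120.2 ml, women 1455.9 ± 115.8 ml —
truncated at zero. Tract FA is then

    fa = baseline(tract) + beta_icv * (icv - mean icv)
                        + beta_age * (age - mean age)
                        + sex_offset * [female] + N(0, noise_sd)

Defaults: per-tract baselines are the sex-averaged whole-group tract FA
means (around 0.30–0.39 across the 14 hemisphere-split tracts), `beta_age`
is −3.0 × 10⁻⁴ FA/year (a typical corpus-callosum-scale aging slope),
`sex_offset` +0.004 FA for women (the order of the observed CC sex
difference), and `noise_sd` 0.011 FA (the observed within-group tract FA
SD). For the ICV slope the voxelwise literature value of 4.7 × 10⁻⁸ is only
physically plausible per mm³; the generator therefore takes `beta_icv` in FA
per **ml** with default 4.7 × 10⁻⁵, which preserves the magnitude of the
effect (≈0.03 FA across the cohort ICV range). Both slopes remain free
parameters rather than assertions about any particular dataset.

Centering in the generator uses the realized cohort means, so ordinary least
squares on noiseless generated data returns the generating coefficients
exactly (to ~1e-10); this estimator/generator consistency is asserted in the
test suite.

## Streamline phantoms

`tract_archetypes()` provides idealized centerlines for the eight tracts
(CC, CG, SLF, ILF, IFO, CST, OR, UNC) in a head-sized frame; they are
geometric stand-ins, not anatomy. `generate_bundle()` displaces a centerline
by a smooth low-order Fourier offset scaled so its maximum pointwise norm is
bounded by the dispersion `radius`, and reverses point order with
probability 0.5 so all downstream code must be orientation-flip safe.
`build_phantom()` adds a small per-subject rigid translation (SD 1 mm) to
emulate inter-individual variation. What the phantom does *not* emulate:
crossing/kissing fibers, partial-volume effects, tractography false
positives, registration error. Passing the recovery tests therefore shows
the clustering machinery is correct on well-posed geometry, not that it
would segment a real tractogram flawlessly.

## Diffusion signal, tensor fit and scalar maps

`simulate_dwi()` uses the mono-exponential tensor model
S = S₀·exp(−b·gᵀDg) over a 45-volume scheme (40 quasi-uniform directions at
b = 1000 s/mm², 5 b = 0), with Rician noise (magnitude of the complex
signal with Gaussian channel noise S₀/SNR) because diffusion MRI magnitude
data is Rician, and `snr = Inf` giving the exact deterministic signal.
`fit_tensor()` is the plain log-linear least-squares estimator — the
simplest member of the standard family, sufficient because no artifact
correction is in scope — and flags voxels with non-positive signals invalid
rather than propagating NaNs. `compute_indices()` yields FA, MD, AD
(= λ₁) and RD (= (λ₂+λ₃)/2); the all-zero tensor gets FA = 0, not NaN, so
background voxels cannot poison downstream statistics.

The skeleton stage is deliberately registration-free: `build_skeleton()`
keeps voxels with mean FA ≥ 0.2 that are local maxima along the discrete
axis of strongest negative curvature of the FA profile, and stores that
axis as the perpendicular search direction; `project_to_skeleton()` takes
the maximum FA within ±5 voxels (configurable cap) along it. This
reproduces the projection contract of skeleton-based voxelwise analysis
without a nonlinear registration machinery, and is idempotent on its own
output.

Head motion: `motion_rms()` computes, per consecutive volume pair with
transforms T₁, T₂, rms = √(R²/5·tr(AᵀA) + tᵀt) with M = T₂T₁⁻¹ − I, on a
sphere of radius 80 mm approximating the head (the framework's standard
radius is not fixed by convention; 80 mm is at the head-sized end and only
scales the rotational term). `rms_mean` averages transitions attributed to
diffusion-weighted volumes, following the reading that b = 0 volumes are
excluded.

## Bundle clustering

The segmentation stage follows the multi-subject consensus scheme:

1. **Resample** every streamline to 25 equidistant arc-length points.
2. **Distance**: d(a,b) = min over the two point orderings of the mean
   corresponding-point Euclidean distance. The source methodology names
   only "pairwise distances"; this corresponding-point form is symmetric,
   flip-invariant, cheap on resampled curves, and is declared as this
   package's choice (the mean-closest-point alternative would tolerate
   partial overlaps better but loses the metric-like behavior on
   equal-length curves).
3. **Ward clustering** of random subsets (paper-scale preset 10,000
   streamlines per subset, 250 clusters; desk-scale tests use 500 and 8).
   Ward linkage is applied to the precomputed streamline distances as if
   they were Euclidean — the standard accommodation when the objects are
   not vectors. The agglomerator (in C++) uses the Lance–Williams
   recursion with merge cost nᵢnⱼ/(nᵢ+nⱼ)·‖cᵢ−cⱼ‖², and breaks exact ties
   by the lowest cluster index pair so results are bit-reproducible; a
   naive O(n³) reference agglomerator computing every merge cost from
   scratch from the original distances serves as the test oracle.
4. **Label matching**: subset 1 of repetition 1 is the global reference;
   every other subset clustering is mapped onto it by minimizing the total
   flip-aligned mean-streamline distance between cluster representatives,
   solved as an optimal assignment (Hungarian, O(k³)).
5. **Consensus** over repetitions (preset 100, tests 10): per-streamline
   modal label, ties to the lowest label; stability = agreement fraction.
   `extract_tract()` prunes at stability ≥ 0.5 by default — majority
   agreement is the natural cut where no threshold is prescribed.

Cluster-to-tract assignment in the synthetic study maps each reference
representative to its nearest tract archetype centerline (one-to-one when
counts match); with real data the tract label sets would come from
configuration, standing in for manual curation.

## Tract metrics

`rasterize_tract()` marks every voxel visited by at least one streamline,
supersampling segments at ≤ 0.25 × the smallest voxel dimension with
half-open voxel boxes and voxel-center coordinates (0-based in the C sense,
1-based in R). A voxel the curve clips for less than one sampling step can
in principle be missed; the tests bound this against a 0.01 mm dense
sampler. Volume = set-voxel count × voxel volume — deliberately exactly the
stated definition, with no morphological filling. `tract_mean_fa()` is the
plain arithmetic mean over the ROI; an empty ROI yields NA and case-wise
exclusion.

## ICV matching

`match_by_icv()` pairs men and women with |ΔICV| < 10 ml (exclusive). Since
it is not recorded whether the original pairing maximized the number of
pairs, this package fixes the contract: maximum cardinality, and among
maximum matchings the smallest total |ΔICV|, computed by a non-crossing
dynamic program over the two ICV-sorted lists (uncrossing preserves both
feasibility and cardinality for threshold matching on a line). The
minimum-difference refinement keeps the matched groups as close in ICV as
the data allow; the matched-group pooled t on synthetic cohorts is then
typically below 0.1. Cardinality optimality is verified against brute-force
enumeration in the tests.

## Statistical layer

* `build_design()` mean-centers continuous covariates (recorded in the
  object); all non-intercept estimates, t, p, η² and permutation p values
  are invariant to centering, and the tests assert this numerically.
* `fit_glm()`: QR least squares; per-term two-sided t tests; partial
  η² = t²/(t²+df) — the Type-III identity for single-df terms.
* `interaction_screen()` adds ICV×sex, ICV×age and sex×ICV×age, corrects
  the interaction p values (BH, one family) and drops those at or above α,
  mirroring the practice of removing interactions when none are found.
  With one observation per subject this OLS screen approximates the mixed
  models a hemisphere-repeated design would use; hemispheres are handled
  as separate responses (left/right tract columns) instead.
* `permutation_inference()` uses Freedman–Lane (residuals of the reduced
  model permuted) — the default scheme of the standard permutation
  framework — with family-wise correction by the max-|t| distribution over
  units or by TFCE-enhanced maxima. Corrected p includes the observed
  statistic: p = (1+#{perm ≥ obs})/(n_perm+1), floored at 1/(n_perm+1).
* `tfce_enhance()`: Σ_h extent(h)^E · h^H · dh with defaults H = 2,
  E = 0.5, dh = max/100 — the established volumetric defaults; skeletonized
  data conventionally use different exponents, so both are arguments.
  Components are found by union-find on an explicit neighborhood edge list,
  and negative contrasts are enhanced separately on the negated map.
* `bh_correct()` applies the standard step-up within each declared family
  (ICV, sex, age effects are separate families in the per-tract reports).
* `cohen_d()` is the unadjusted two-group pooled-SD d with the women−men
  sign convention, also computable from printed summary statistics; whether
  to covariate-adjust d is left open in the source methodology, so the
  plain two-group form is used and documented.

## The orchestrated study

`run_study()` chains the stages under a single master seed with
counter-based per-stage seed derivation, so a stage can be rerun in
isolation and the whole run (including the JSON summary) is byte-identical
for identical configuration. Its statistics run on the forward-model
subject table; the phantom path (clustering → consensus → rasterization)
runs on a small number of phantom subjects and reports recovery quality
(adjusted Rand index against ground truth) and per-tract volumes. Per-tract
tractography volumes for every cohort subject would require cohort-scale
tractograms, which is outside the synthetic replica's scope.

Problem sizes: the default desk-scale study uses 60 subjects, 8 bundles ×
100 streamlines × 2–3 phantom subjects, 10 clustering repetitions and a few
hundred permutations; the verification runs use 3 × 8 × 200 streamlines
(subset size 500, 10 repetitions), n = 2000 cohorts for parameter recovery,
and 200 replicates × 2000 permutations × 500 units for the family-wise
error calibration. These sizes make every property checkable on a
single-core desktop in minutes while leaving the paper-scale presets
(10,000-streamline subsets, 250 clusters, 100 repetitions, 5000
permutations) available through configuration.

## Known limitations

* Phantoms are geometric archetypes; no crossing-fiber geometry, no
  scanner or registration artifacts, no real anatomy.
* The skeleton builder is a local ridge detector, not a registration-based
  group skeleton; it shares only the projection contract with TBSS.
* The Ward/consensus pipeline assumes bundles are compact in the chosen
  streamline metric; heavily overlapping or branching tracts would need
  the manual curation step the synthetic replica replaces with
  archetype-nearest assignment.
* `fit_tensor()` has no weighting or outlier rejection; it is not meant
  for artifact-laden data.
* All group-level numbers produced here describe synthetic cohorts only.
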