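# bundlekit

Streamline bundle clustering and cohort statistics for diffusion MRI.

Population studies of white-matter microstructure relate diffusion tensor
imaging (DTI) indices — fractional anisotropy (FA), mean/axial/radial
diffusivity (MD, AD, RD) — to subject covariates such as intracranial
volume (ICV), sex and age. bundlekit implements the full analysis chain for
such a study as a tested, reusable R package:

* **Tensor metrics** — log-linear tensor fitting from DWI + gradient
  scheme, the four scalar indices, a registration-free white-matter
  skeleton (FA ≥ 0.2 ridge) with perpendicular maximum-FA projection, and
  scan-to-scan RMS head-motion summaries.
* **Bundle clustering** — multi-subject consensus segmentation of
  tractography streamlines: resampling to 25 points, flip-invariant
  pairwise distances, Ward agglomeration of random 10,000-streamline
  subsets into 250 clusters (desk-scale presets configurable), optimal
  cross-subset label matching, and a modal-label consensus with
  per-streamline stability over repeated random partitions.
* **Tract metrics** — voxel rasterization of extracted tracts, tract
  volume (set-voxel count × voxel volume) and mean FA.
* **Cohort statistics** — maximum-cardinality ICV-matched pair
  construction (|ΔICV| < 10 ml), mean-centered multiple regression
  `fa ~ icv + age + sex` with interaction screening, permutation inference
  (Freedman–Lane; max-statistic or TFCE family-wise correction),
  Benjamini–Hochberg correction within effect families, Cohen's *d* and
  partial η².
* **Synthetic data** — geometric phantoms for 8 tract archetypes (CC, CG,
  SLF, ILF, IFO, CST, OR, UNC), a Rician-noise DWI simulator, and a
  forward cohort model

      fa = baseline + β_icv·(icv − mean) + β_age·(age − mean)
                    + sex_offset·[female] + N(0, σ)

  with sex-specific ICV distributions (men 1667.9 ± 120.2 ml, women
  1455.9 ± 115.8 ml) and ages uniform on 50–66, so every downstream stage
  is testable without subject data.

The core statistics in the field's notation: FA =
√(½)·√(((λ₁−λ₂)² + (λ₂−λ₃)² + (λ₁−λ₃)²)/(λ₁²+λ₂²+λ₃²)); Ward merge cost
nᵢnⱼ/(nᵢ+nⱼ)·‖cᵢ−cⱼ‖² on streamline distances treated as Euclidean;
TFCE(v) = Σ_h e(h,v)^0.5·h²·dh; corrected permutation
p = (1+#{max-stat* ≥ obs})/(n_perm+1).

## Worked example

```r
library(bundlekit)

# A printed-summary t test: ICV difference between 383 men and 429 women
res <- two_sample_t(list(n = 383, mean = 1667.9, sd = 120.2),
                    list(n = 429, mean = 1455.9, sd = 115.8))
sprintf("t = %.1f, df = %d, p = %.3g", res$t, res$df, res$p)
#> "t = 25.6, df = 810, p = 3.01e-106"

# A seeded end-to-end synthetic study: 60 subjects, 8-bundle phantom,
# consensus clustering, matching, regression + permutation statistics
out <- run_study(study_config(seed = 42))
out$summary$clustering$adjusted_rand     # phantom recovery vs ground truth
#> 1
head(render_report(out$stats)$age, 4)
#>    tract      beta p_adjusted eta_sq_partial
#> 2     cc -0.000613      0.266         0.0440
#> 5     cg -0.000254      0.549         0.0128
#> 26 cst_l -0.000746      0.130         0.0951
#> 29 cst_r -0.000531      0.266         0.0467
out$tract_table[1:3, ]
#>   tract n_streamlines volume_mm3 mean_fa
#> 1    CC           300       5992  0.4123
#> 2    CG           300       4648  0.4299
#> 3   SLF           300       5160  0.4607
```

An adjusted Rand index of 1 means the consensus segmentation recovered the
eight phantom bundles exactly. The `age` table is the per-tract regression
report (unstandardized slope in FA/year, BH-corrected p within the age
family, partial η²); at n = 60 the default −3×10⁻⁴/year slope is below the
detection threshold, as the wide p values show. Tract volumes are in mm³ on
the phantom grid.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/bundlekit.R run   --config study.json --out results/
Rscript inst/scripts/bundlekit.R stats --table cohort.csv  --out stats.csv
```

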