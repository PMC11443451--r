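# venalamina

Laminar vessel-distance analysis of cortical microstructure.

## What problem this solves

Quantitative 7T MRI maps of the cortex — longitudinal relaxation time (qT1,
ms; a myelin proxy) and quantitative susceptibility (QSM, ppm; its positive
values track iron, its negative values calcium/protein) — vary not only with
cortical depth but with the distance of each voxel to the nearest vein. A
study of cortical ageing that ignores the local venous architecture
therefore confounds vascular geometry with tissue microstructure.
`venalamina` implements the full analysis chain that resolves this:

1. **Vein segmentation** — a multiscale Hessian (Frangi-type) tubularity
   filter turns a susceptibility volume into a vessel probability map
   (externally computed maps are also accepted); a 3-class Otsu histogram
   analysis returns a lower and an upper threshold, maximizing the
   between-class variance `σ_B² = Σ_k ω_k (μ_k − μ_T)²`; hysteresis
   binarization keeps a mid-band voxel only if it is 26-connected, through
   voxels above the lower threshold, to a voxel above the upper threshold.
2. **Vessel distance mapping (VDM)** — an exact Euclidean distance
   transform (anisotropic, no chamfer approximation) gives each voxel its
   distance in mm to the nearest vein voxel; vein voxels themselves are
   excluded from all metric sampling.
3. **Equi-volume laminar depths** — each ribbon voxel gets a depth fraction
   from the equi-volume model
   `ρ(α) = (−A_i + √(α A_o² + (1−α) A_i²)) / (A_o − A_i)`
   (local areas estimated from the mean curvature of the outer boundary's
   level set), discretized into 21 depths; the 3 most superficial and the 2
   deepest are excluded and the remaining 16 are averaged into four
   compartments (SF / OM / IM / DP).
4. **Distance binning** — five half-open 2-mm bins (0–2 … 8–10 mm), with a
   minimum of 4 voxels per cell; positive and negative QSM are split and
   binned separately.
5. **Statistics** — mixed-design repeated-measures ANOVA (between: age
   group; within: area × depth compartment × distance bin) with both the
   univariate Greenhouse–Geisser and the exact multivariate path (the
   latter reproduces the df pattern (4, 30), (3, 31), (1, 33) at
   N = 35, g = 2), generalized eta-squared effect sizes, Holm–Bonferroni
   step-down post hocs with Hedges-corrected Cohen's d and bootstrap
   percentile CIs, Monte-Carlo permutation Welch tests, monotone multiple
   imputation of the closest bin with D2 pooling, profiled-ML
   random-intercept models with likelihood-ratio comparisons, and Pearson
   correlations of pQSM vs qT1.

Because the source cohort's MRI data are not openly deposited, the package
ships a **synthetic phantom cohort generator**: folded cortical ribbons
pierced by bright tubular veins, with qT1/QSM fields carrying programmed
depth gradients, per-group vein-distance slopes, a U-shaped iron-distance
profile, between-subject variance and voxel noise, all calibrated to the
published cell means and SEMs. Every pipeline stage is tested against that
known ground truth.

## Worked example

```r
library(venalamina)

spec <- phantom_spec(n_young = 8, n_old = 7,
                     grid_shape = c(48, 48, 40), spacing = 0.5,
                     fold_amplitude = 2, fold_wavelength = 24,
                     n_veins = 2, vein_min_sep = 10, vein_margin = 4)
cfg <- study_config(phantom = spec, seed = 7,
                    B_perm = 2000, B_boot = 200, m_imputations = 3)
report <- run_study(cfg, "readme_run")

a <- read.delim("readme_run/anova_qt1_4bins.tsv")
print(a[, c("effect", "DFn_mv", "DFd_mv", "F_mv", "p_mv", "eta2_G")],
      digits = 3, row.names = FALSE)
```

```
                    effect DFn_mv DFd_mv     F_mv     p_mv   eta2_G
                     group      1     12 6.72e+00 2.36e-02 0.348303
                      area      1     12 4.29e+02 9.26e-11 0.096352
                     depth      3     10 4.29e+04 7.70e-21 0.878192
                  distance      3     10 4.02e+01 6.90e-06 0.077421
            group:distance      3     10 6.11e+01 9.81e-07 0.107915
       group:area:distance      3     10 2.11e-01 8.86e-01 0.000157
 ...
```

This is the four-distance-condition analysis (closest bin excluded) of a
15-subject scaled phantom. The rows to read: the phantom programs a strong
laminar gradient (`depth`, η²G = 0.88), an areal qT1 offset (`area`), a
distance main effect, and opposite-sign qT1-vs-distance slopes in the two
age groups — detected as the large `group:distance` interaction
(F(3,10) = 61.1, p ≈ 1e-06), the central published finding the generator
emulates. Noise-only effects (e.g. `group:area:distance`) stay
non-significant. The same run writes the imputed five-bin ANOVAs, post hoc
tables, permutation tests, random-intercept model comparisons, correlations,
a cohort manifest, and a JSON provenance report with every seed.

A command-line front end covering each stage separately
(`simulate`, `segment-veins`, `vdm`, `depths`, `extract`, `stats`,
`run-all`) is installed at `inst/cli/venalamina`.

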