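---
title: "Methods: laminar vessel-distance analysis and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar vessel-distance analysis and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices, numerical decisions, and the limits of what its green tests
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The scientific object is the dependence of cortical microstructure maps —
qT1 (ms, inversely related to myelin) and signed QSM (ppm; positive values
a cortical iron proxy, negative values a calcium/protein proxy) — on two
spatial coordinates: the equi-volume cortical depth and the Euclidean
distance to the nearest vein. The analysis discretizes both (four laminar
compartments from 21 depths; five 2-mm distance bins), averages metric
values per (participant, area, compartment, bin) cell, and treats the cell
means as a mixed repeated-measures design with age group between subjects.

### Vein segmentation

The vessel probability map comes from a multiscale Hessian tubularity
filter (bright tubular structures; plate and blob terms with
`alpha = beta = 0.5`, structure term with `c` at half the maximal Frobenius
norm per scale, scale normalization `sigma^2`, maximum over scales,
min–max rescaled to [0, 1]). This is a stand-in: the original vessel filter
in the source toolchain is a Markov-random-field diffusion technique whose
internals are not published; everything downstream of the probability map
is faithful, and an externally supplied probability map can be passed in
(`segment_veins(prob = ...)`).

Thresholds are a 3-class Otsu analysis: exhaustive search over all
histogram bin-boundary pairs for the two thresholds maximizing the
between-class variance, 256 bins over the observed range by default,
computed within a ribbon mask when provided — the probability map is
near-zero almost everywhere, and unmasked histograms would let the
background class dominate the weights. Ties break toward the smaller
thresholds. Hysteresis binarization uses 26-connectivity with paths
constrained above the lower threshold; connectivity is not stated in the
source description, so standard hysteresis semantics were chosen.

A deliberate negative result is recorded here: a volume with *no* veins
does not produce an empty mask — the adaptive threshold chain finds noise
structure instead, which is also the behavior of the real tools. The
pipeline therefore refuses vein-free phantom configurations up front
rather than pretending the segmenter would detect their emptiness.

### Vessel distance mapping

The distance map is the exact Euclidean distance transform (separable
lower-envelope algorithm, anisotropic spacing, compiled), measured between
voxel centers. Vein voxels are 0 and excluded from sampling, which is why
the closest analysis bin starts just above zero: the bin "0–2 mm"
operationally means `0 < d <= 2`. Chamfer or other approximate transforms
are rejected by the brute-force oracle test.

### Equi-volume depths

Depth runs from 0 at the GM/CSF boundary to 1 at the WM/GM boundary. The
equidistant fraction is `d_outer / (d_outer + d_inner)`. The equi-volume
coordinate is the volume fraction at the voxel's Euclidean position in a
local wedge whose cross-sectional area varies linearly between the two
boundaries; the wedge's area ratio is estimated from the mean curvature
`H` of the outer boundary's level set through the voxel
(`A_o = 1 + H t`, `A_i = 1 − H (T − t)`), with `H` from the divergence of
the normalized gradient of the outer signed-distance volume.

One orientation subtlety deserves a paragraph, because the surrounding
literature is easy to misread. The standard closed-form
`rho(alpha) = (−A_i + sqrt(alpha A_o² + (1 − alpha) A_i²)) / (A_o − A_i)`
measures both `rho` and `alpha` *from the boundary whose area is `A_i`*:
its own frustum integration confirms this (`A_i = 1, A_o = 2,
alpha = 0.5` gives `rho = 0.5811` — more than half the Euclidean span must
be crossed from the small-area side to enclose half the volume). Applying
the formula from the outer boundary therefore swaps the area roles. The
physical consequence, validated against numeric integration and the
spherical-shell closed form, is that at a gyral crown (outer area larger)
the equi-volume depth at the Euclidean midpoint is *deeper* than 0.5:
volume accumulates faster on the large-area side, equal-volume layer
boundaries crowd toward the pial surface, and superficial layers thin —
the classical laminar-conservation behavior. `equivolume_fraction()` keeps
the literature formula and convention; `compute_depth_field()` applies it
in the correct frame. The inverse is closed-form (the relation is
quadratic under the square root), which exceeds the 1e-8 tolerance a
numerical inversion would be held to.

Voxels where the wedge degenerates (`A <= 0`, i.e. `|H|` large relative to
the local thickness — sulcal fundi and crown crests of strongly folded
geometry) fall back to the equidistant fraction; the count is attached to
the returned field. The curvature estimate is finite-difference and
underestimates sharp curvature; the correction's direction is validated,
its magnitude is approximate.

Two resolution caveats bound what the depth tests establish. First, the
uniformity advantage of equi-volume binning (smaller coefficient of
variation of per-depth-bin voxel counts) is only measurable when the depth
coordinate is sampled finer than the bin width; at the analysis resolution
(a 3 mm ribbon at 0.5 mm, ~6 voxels across), bin-boundary aliasing
dominates the counts for either model. The dedicated test therefore uses
an anisotropic fine-z grid. Second, exact compartment balance on a flat
ribbon requires voxel layers to tile depth bins exactly; the balance test
constructs that alignment deliberately.

### Sampling and the condition table

Cell values are voxel means (the published tables are mean/SEM
structured; median aggregation is not implied anywhere). Bins are
half-open `(prev, next]`, matching labels that place 2.00 mm in the closer
bin and 2.01 mm in the next. The minimum-voxel rule (4) is applied per
metric to the sign-split QSM counts separately, so a cell can be present
for qT1 but missing for nQSM. Distances use the single global vein mask
(one distance map multiplied by depth and area masks), not depth-restricted
vein subsets.

## The statistics engine

Within-subject effects are tested on orthonormal contrast scores
`Z = Y C`, with `C` a Kronecker product of per-factor orthonormalized
Helmert contrasts and normalized unit vectors. Two paths are reported for
every effect:

* **univariate**: split-plot sums of squares (traces of the hypothesis and
  residual SSCP), Greenhouse–Geisser epsilon
  `(tr S)² / ((k−1) tr S²)` from the pooled residual covariance of the
  scores, clipped to `[1/(k−1), 1]`, reported unconditionally alongside
  the uncorrected test (no sphericity pre-test gates anything);
* **multivariate**: the exact Hotelling-type F with
  `DFd = N − g − p + 1`, which is the path that reproduces the integer
  denominator degrees of freedom (4, 30), (3, 31), (1, 33) printed for
  N = 35, g = 2. Which published rows used which correction is not stated
  in the source; reporting both avoids guessing.

The within-main-effect hypothesis uses the sample-size-weighted grand
mean. With two groups this coincides with the unweighted (Type III) test
for every group-involving effect, and it makes the sums-of-squares ledger
exactly orthogonal: the corrected total SS equals the sum of all effect
and error SS to machine precision even at n = 18 vs 17. Generalized
eta-squared is computed from that ledger
(`SS_effect / (SS_effect + SS_subjects + Σ SS_within-error)`), the only
definition available regardless of which F path is displayed.

Post hoc families: consecutive-bin paired t-tests (overall and per area;
family size 4) and per-bin between-group Welch tests (family size 5), each
Holm-adjusted within family, with Hedges-corrected d
(`J = 1 − 3/(4 df − 1)`) and seeded percentile-bootstrap CIs (B = 2000
default; the source states the percentile method but no B). Degenerate
bootstrap resamples at tiny n are dropped from the interval rather than
aborting. Identical paired samples return `t = 0, p = 1`; a constant
nonzero paired difference is treated as a degenerate input and is fatal.

Permutation Welch tests use the `(1 + #{|t*| ≥ |t_obs|}) / (1 + B)`
estimator — guaranteed valid, differing from other tools' estimators by
O(1/B), immaterial at the production B = 100 000.

Missing closest-bin cells are completed by monotone regression imputation:
per incomplete column (fewest missing first), a regression on the complete
columns of the same (area, compartment) stratum plus group, with residual
variance drawn from its scaled inverse chi-square and coefficients from
their sampling distribution, per completed dataset — the
"regression-with-noise with parameter draws" variant, since the exact
historical implementation is not specified. ANOVAs over the m = 5
completed datasets are pooled by the D2 rule on `DFn · F`; identical
tables pool to their common F (with an infinite reference df2). The D2
statistic is *not* guaranteed to stay above the per-imputation minimum F —
the between-imputation variance penalty can push it lower — so the
retained-range diagnostic asserts only the upper bracket.

Random-intercept models are fitted by profiled maximum likelihood: for a
fixed variance ratio `lambda = sigma_b²/sigma²`, GLS estimates and the ML
log-likelihood have closed forms under compound symmetry (per-participant
rank-one updates); `lambda` is maximized by a 1-D search on the log scale
with the OLS boundary always evaluated. The fit matches `lme4` ML
log-likelihoods to 1e-5 in the test oracle. Comparisons are
likelihood-ratio chi-squares on the fixed-parameter count difference:
risk vs null has df 1, the risk-by-distance model vs null df 5 (risk plus
four interaction terms for a 5-level bin factor).

## The phantom: what it emulates, and what it does not

A cohort of 18 young / 17 old subjects (risk prevalence 9/17 in the old
group), each a folded ribbon (sinusoidal outer surface, amplitude 3 mm,
wavelength 24 mm, thickness 3 mm at 0.5 mm isotropic spacing on a
96×96×64 grid) with two areas by coronal split and near-vertical cylinder
veins (default 6 veins of 1.0 mm radius, 10 mm minimum separation). The
vein radius is a realism choice: at 0.5 mm isotropic resolution only veins
of roughly two voxels diameter and above are segmentable, and detected
pial veins are typically 1–3 mm across.

Metric fields are additive effect models with distance centred at 5 mm
and depth at 0.5, so ANOVA effects map one-to-one to generator
parameters. Defaults are calibrated to the published cell tables:

* qT1: areal baselines 1692/1736 ms; depth slope −650 ms per unit depth
  fraction (superficial 1898 → deep 1524 ms over the retained range);
  distance slopes −13.5 (young) and +1.6 (old) ms/mm — ordinary
  least-squares fits to the published age-by-distance cell means, whose
  difference *is* the programmed interaction; old-group offset −24 ms;
  between-subject SD 55 ms (so cell SEMs land in the printed 11–24 ms
  range at n = 17–18); voxel SD 80 ms.
* QSM: a per-voxel Bernoulli sign mixture (p_pos = 0.6) so that positive
  and negative QSM extraction are both exercised — an analysis device, not
  a susceptibility physics model. Positive magnitudes carry areal
  baselines 0.0130/0.0102 ppm, depth slope −0.0074 ppm, old-group offset
  +0.0047 ppm, and a U-shaped distance curvature of 1.3e-4 ppm/mm²
  (least-squares on the published bin means); the negative branch mirrors
  the construction with its own draws. Magnitudes are floored at 1e-4 ppm.
* The published record gives no voxel-level noise figure — only cell
  SEMs — so the voxel SDs are calibrations to land simulated SEMs in the
  printed range, flagged as such, not ground truth.

Veins are bright on QSM (0.3 ppm), which is what the vesselness filter
detects. Geometry is shared across subjects; veins, subject intercepts and
noise are per-subject, each from a sub-seed derived deterministically from
the master seed.

Not emulated: MR physics (no B0, no dipole convolution, no Rician bias),
arterial trees, realistic gyrification, registration error, or
segmentation error of the cortical boundaries (the phantom supplies exact
surfaces). A green end-to-end test therefore establishes that the
*computational chain* recovers programmed effects through segmentation,
distance mapping, laminar sampling and statistics — not that the chain is
robust to acquisition artifacts it never sees.

## Scaled test worlds

Two reduced configurations appear in the tests, chosen once for
tractability: a 48×48×40 half-scale ribbon (15 subjects) for end-to-end
runs — determinism and output structure do not depend on scale — and the
16³-per-subject cohort at 1.25 mm spacing (thickness 5 mm, one 1.25 mm
vein) for the interaction-recovery criterion, where the grid margin
requirement is interpreted as a two-voxel clearance (a ten-voxel margin
cannot coexist with any ribbon on a 16-voxel axis). Recovery tests read
the truth fields (analytic vein distances, generative depth) rather than
re-running segmentation, isolating the statistical recovery being
measured; segmentation accuracy is tested separately (Dice ≥ 0.6 against
truth within the ribbon at default settings, typically ≈ 0.9).

## Numerical choices

* Surfaces: signed distances from a two-sided exact EDT against the
  voxelized boundary with a half-voxel correction; accuracy within one
  voxel diagonal of brute-force point-to-surface search.
* Otsu: exhaustive over all C(n_bins−1, 2) pairs via cumulative sums;
  exact tie-break toward smaller thresholds.
* Hysteresis: iterative 26-neighbour dilation to fixpoint (equals BFS
  flood fill; oracle-tested).
* GG epsilon at its lower bound and eta-squared at [0, 1] are enforced by
  clipping; zero-variance inputs are fatal rather than silently NaN.
* All stochastic procedures (cohort, permutation, bootstrap, imputation)
  draw from named sub-seeds derived from one master seed and recorded in
  the JSON run report; two runs with one seed produce bit-identical TSVs.

## Known limitations

* The curvature-based area-ratio estimate is first-order; strongly curved
  voxels fall back to equidistant layering (counted, reported).
* The Frangi-type stand-in is not the original vessel filter; probability
  maps from the original tool can be supplied instead.
* The multivariate path's exact F covers rank-one hypotheses (two groups);
  more groups would engage a Hotelling–Lawley approximation.
* The imputation fallback (intercept + group) activates at very small
  cohort sizes and is reported via warnings and the run notes.
* pQSM/nQSM post hoc Holm multipliers in the source are mutually
  inconsistent for one family; validation rests on the two internally
  consistent qT1 families.
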