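---
title: "Methods: lesion topography and rehabilitation outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion topography and rehabilitation outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`LesionTopo`, in the spirit of a statistical methods section. The package
relates binary stroke-lesion masks in a common standard space to change
scores of three gait measures — walking speed (m/s), the Functional
Ambulation Category (FAC, ordinal 0–5) and the Modified Rivermead Mobility
Index (MRMI, ordinal 0–40) — adjusting for age (years), Fazekas white-matter
score (ordinal 0–3, entered numerically), days from stroke to baseline, and
the analysed measure's baseline score.

## Coordinate and data conventions

All volumes are `VolumeGrid` objects: a 3-D array plus a 4×4 NIfTI-style
affine mapping 0-based voxel indices to mm. In R code, indices are the
native 1-based array indices and the affine is applied to `index - 1`;
world coordinates are mm with x increasing to the anatomical right. "Slice
z" always means an axial plane (third index). Masks are strictly binary;
values outside {0, 1} are binarized at > 0 with a warning, because
delineation tools emit 0/1 and 0/255 interchangeably.

Right-sided lesions are mirrored onto the left hemisphere about the
mid-sagittal plane x = 0 mm before any pooled voxelwise analysis. The
reflection is an index-space reversal of the first axis, which is exact only
when that axis is aligned with world x and the grid is symmetric about x = 0;
oblique or off-centre grids are rejected rather than silently resampled,
since resampling would blur a binary mask. Flipping is an involution and
preserves the lesioned-voxel count exactly.

## Weighted tract lesion load

For a canonical binary tract with axial cross-sectional areas
`A(z) = (tract voxels on slice z) × in-plane voxel area` and maximum
`A_max`, a lesion's weighted load is

    wCST-LL = sum_z o(z) * A_max / A(z) / 1000   [cm^3]

with `o(z)` the lesion∩tract overlap volume (mm³) on slice z. Weights are
≥ 1 by construction, and slices where `A(z) = 0` cannot contribute because
`o(z) = 0` there. The areas come from the binarized tract on the analysis
grid, not from a continuous model, matching how canonical tracts are built
(binarized, summed single-subject tracts). A lesion with no voxel on any
slice of the tract's support — e.g. a medullary lesion below a
supratentorial template — is flagged `outside_tract_support` and its load
reported as missing; downstream regressions exclude such subjects rather
than scoring them 0. The load is monotone in the lesion, additive over
disjoint lesions, and reduces to plain overlap volume for a constant-area
tract; all three properties are tested, together with a brute-force
per-voxel oracle (agreement to 1e-9 cm³).

## Voxel-based lesion–symptom mapping

**Search volume.** A voxel is tested when lesioned in at least
`minLesioned` subjects (default 6) *and* spared in at least 2; a voxel
lesioned in everyone has no comparison group. Raising the floor to 10 is
the first standard sensitivity rerun.

**Voxel model.** At voxel v, `score = b0 + bL·lesion_v + covariates + e`
by least squares; the reported statistic is the t of `bL`, sign-flipped so
positive t means lesioned subjects score lower after adjustment. The
implementation uses the Frisch–Waugh residualization
(`t = f(L'My, L'ML, Y'MY)` with M the covariate residual-maker), which is
algebraically identical to the full normal equations and is verified
against a direct least-squares oracle to 1e-8 at every search voxel; with
no covariates it reduces exactly to the pooled-variance two-sample t.
Residual df = n − (number of model columns) is constant over voxels; voxels
where `L'ML ≈ 0` (lesion indicator collinear with covariates) or the
residual variance vanishes are flagged inestimable and removed from the
search volume with a log entry. FAC and MRMI change scores enter this
voxelwise model as numeric responses — the convention of the standard VLSM
framework — while the ordinal machinery is reserved for the tabular
battery.

**Clusters.** The cluster-forming threshold converts the uncorrected p
(default 0.005) to a Student-t quantile at the model df, one-sided in the
damage-lowers-score direction by default (a two-sided option thresholds
|t|). Supra-threshold voxels are grouped by 26-connectivity (the most
inclusive standard neighbourhood; 6 and 18 are available, and two voxels
touching only at a corner are one cluster at 26 but two at 6). Each cluster
reports size (voxels and mL), peak t with its mm coordinate, and the
unweighted mean of member mm coordinates as centre of mass. Connected
components are checked against an independent graph-components oracle.

**Permutation correction.** The null statistic is the maximum t over the
whole, fixed search volume — not only over supra-threshold voxels — so
there is no circularity, and it is well defined even when a permutation
yields no cluster. Behavioural rows (score and covariates *jointly*) are
shuffled against the masks, the plain reading of "permuting the measures
between subjects"; a Freedman–Lane residual-permutation variant is
available behind `freedmanLane = TRUE` but is not the default. Corrected
p = (1 + #{permutation max ≥ peak t}) / (B + 1), which is bounded below by
1/(B+1), monotone in peak t, and matches exhaustive enumeration on an
n = 6, single-voxel cohort within Monte-Carlo error. Family-wise error on
null cohorts is verified to land in a binomial band around the nominal
0.05. Whether the original analyses of this design permuted covariates
together with scores is generally unstated in the field; joint permutation
was chosen as the declared default, with the residual scheme as the
alternative.

**Reruns.** Sensitivity reruns are pure configuration changes
(`minLesioned = 10`, `pUncorrected = 0.001`); on the implanted-effect
fixture the same cluster persists with smaller extent. Leave-one-out
stability drops one subject at a time and reports the displacement of the
matched significant cluster's centre of mass, with folds lacking a
significant cluster reported as missing; the conventional summary counts
folds within 1.4 mm. Per-hemisphere splits rerun the stage on each side's
subset, skipping subsets below a minimum size.

## Tabular statistics

- **Kendall tau.** Tau-b, because ties are guaranteed on ordinal scales;
  the variant is a declared choice since descriptive conventions differ.
  Verified against O(n²) pair counting with tie correction.
- **Wilcoxon effect size.** Signed-rank test on paired baseline/outcome:
  zero differences dropped, average ranks for ties, tie-corrected normal
  approximation without continuity correction, and r = |Z|/√N with N the
  pairs entering the test. (The effect-size formula is sometimes printed
  garbled as "r² = Z√N" in the applied literature; r = Z/√N is the cited
  convention and is what is implemented.)
- **Multiple regression.** OLS with standardized betas
  `b·sd(x)/sd(y)`, two-sided coefficient p, raw Pearson r, and partial
  r = t/√(t² + df), verified against residual-on-residual correlation.
  Fazekas and FAC baseline enter as numeric scores so tables keep one row
  per covariate. Rank deficiency is an error naming the collinear columns.
- **Ordinal regression.** Proportional-odds cumulative-logit model by
  maximum likelihood (`MASS::polr`); logit link, because odds-ratio
  reporting implies it. OR = exp(coef) is the odds of a *higher* outcome
  category per unit of the predictor; Wald χ² = (coef/se)², CI =
  exp(coef ± 1.96·se). Responses with fewer than three observed categories,
  non-convergence, and separation (unstable SEs) are flagged, not fitted.
  Note the proportional-odds model only *approximates* a logistic fit of
  any single dichotomization when the response has 3+ categories; exact
  equality holds only for a truly binary response, which `polr` (and the
  stated precondition) excludes.
- **Quantiles.** Medians and IQRs use the linear-interpolation convention
  (R type 7), stated because software conventions differ.
- No multiple-testing correction is applied across the descriptive
  correlation table, which is descriptive by design.

## The synthetic cohort

The generator's defaults describe the emulated study conditions: 50
subjects on a 32³ grid of 2 mm isotropic voxels (the grid symmetric about
the origin so flipping is exact), lesion centres drawn from a 3-D Gaussian
(SD 7 mm) around a left striatocapsular hotspot, radii uniform on 5–14 mm
with a 12% ragged-boundary jitter — yielding a single spatial mode of the
overlap-count map at the hotspot with a maximum per-voxel overlap of
roughly 24 of 50. Covariates: age U(35, 90), Fazekas categorical with
probabilities (0.30, 0.35, 0.25, 0.10), delay U(7, 42) days, baseline
walking speed U(0.05, 1.0) m/s.

Walking change is linear in the lesion's overlap (mL) with a designated
5×5×6-voxel effect region straddling two atlas parcels:
`0.65 − 0.35·overlap − 0.2·baseline − 0.003·age − 0.002·days + N(0, 0.08)`,
truncated so outcome speed is non-negative. The intercept and noise were
chosen once so that mean improvement is a realistic ~0.15 m/s; the effect
size makes full effect-region destruction cost about 0.4 m/s. FAC and MRMI
outcomes threshold latent responses
`−2·overlap + 1·baseline − 0.04·age + Logistic(0, 1)` at fixed cutpoints
(FAC: −6, −4.5, −3, −1.5, 0; MRMI: a unit grid shifted so typical
improvement is a few points), which makes proportional-odds recovery exact
by construction. One master seed drives per-subject substreams
(`seed + 1000003·i mod 2³¹−57`), so extending the cohort never perturbs
existing subjects. `makeNullCohort()` zeroes both lesion coefficients,
leaving geometry and covariates bit-identical — the basis of the
family-wise-error calibration.

What the simulation does *not* emulate: vascular-territory lesion shapes
(blobs suffice for the statistics under test, and exact oracles are easier
on simple geometry), registration or segmentation error, MRI signal, or
more than two timepoints. Passing tests therefore validate the statistical
machinery, not robustness to real-data artefacts such as correlated
mislabelling of lesion boundaries. The synthetic tract is a vertical tube,
wide at the top and narrowest mid-course, so the slice weighting is
non-trivial; the quadrant "atlas" is a 4-parcel tiling whose only purpose
is to exercise percent-overlap reporting, including the effect region
straddling two parcels.

## Numerical choices and problem sizes

Inestimability cutoffs: `L'ML > 1e-8` and residual sum of squares
`> max(Y'MY, 1)·1e-12`. Grid-compatibility checks use 1e-6 mm on affines.
Cluster ties: the peak is the first voxel attaining the maximum in
column-major order (ties are measure-zero for continuous scores). Empty
search volumes, empty cluster lists, lesions outside the tract support,
constant variables in correlations, and all-zero difference vectors are all
explicit, flagged results rather than errors or silent zeros.

Validation problem sizes were fixed in advance to keep the full suite
within a few minutes on one CPU: brute-force load oracles on 100 random
20³ lesion/tract pairs; t-map oracles at every search voxel of a 40-subject
32³ fixture; permutation exactness at B = 2000 against the 720-permutation
enumeration; family-wise error over 200 null cohorts (n = 40) at B = 500;
effect recovery on the default 50-subject fixture at B = 1000; linear
recovery over 100 replicate cohorts; ordinal bias at n = 60/120/240 with
200 replicates each and type-I error over 200 nulls. The acceptance script
reuses the same designs with 100 null cohorts.

## Known limitations

Atlas labels are only as fine as the atlas: coarse parcels (e.g. an
"insula" label that also covers the external capsule and claustrum)
overstate specific structures, and no correction is attempted. The package
assumes masks are already in a common space — no registration, resampling
or segmentation is provided. Oblique tract axes are out of scope for the
slice weighting, which is defined on axial planes. Permutation p-values are
Monte-Carlo estimates with floor 1/(B+1); leave-one-out reruns inherit that
granularity. The voxelwise model treats ordinal change scores as numeric,
which is standard for VLSM but approximate for short scales like FAC.
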