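---
title: "Quantitative MRI biomarkers of the disc-endplate complex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI biomarkers of the disc-endplate complex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineqmr)
```

## The scientific problem

Nucleus pulposus (NP) cells are fed by nutrients that diffuse from the
vertebral capillary bed, across the cartilage endplate (CEP), into the disc.
Two tissue properties gate that supply: the composition of the CEP (its
permeability) and the state of the adjacent vertebral marrow (its
perfusion). Both are measurable in vivo with quantitative MRI:

* **CEP T2\*** from multi-echo ultra-short echo-time (UTE) imaging — lower
  values reflect lower hydration and glycosaminoglycan content and a higher
  collagen-to-GAG ratio, i.e. a less permeable endplate;
* **vertebral bone-marrow fat fraction (BMFF)** from chemical-shift
  water-fat imaging — higher values mean fattier, less vascular marrow;
* **NP T1ρ** from spin-lock imaging — a continuous proteoglycan-sensitive
  measure of disc degeneration severity (lower = more degenerated).

`spineqmr` implements the full quantitative pipeline from image series to
per-endplate biomarkers and their statistical associations, together with
synthetic phantom and cohort generators that make every stage testable
against known ground truth. The `analysis/` scripts in the source tree run
the pipeline end to end and write their tables under `results/`.

## Relaxometry

Both relaxation contrasts share one model: a mono-exponential decay
$S(t) = S_0 e^{-t/\tau}$ sampled at echo times (TE, for T2\*) or spin-lock
times (TSL, for T1ρ), fitted per voxel by `fit_decay()`.

The default fitter runs weighted log-linear least squares (weights $S^2$,
the standard variance-stabilising choice in the log domain) and refines the
result by untransformed Levenberg-Marquardt least squares, vectorised
across voxels. Design choices:

* **Noise floor.** Voxels with any nonpositive sample are flagged invalid
  rather than clamped; clamping before the log transform biases $\tau$.
* **Bounds and quality.** Defaults $\tau \in [1, 200]$ ms and
  $r^2 \ge 0.7$; both configurable. The acquisitions do not prescribe
  quality thresholds, so these are deliberately conservative and surfaced
  in the interface.
* **Numerical behaviour.** On noiseless data the log-linear step is already
  exact (the model is linear in the log domain), and the refinement leaves
  it unchanged to better than $10^{-6}$ relative. Against a dense
  grid-search oracle (with $S_0$ profiled out) the refined fit agrees to
  well under 0.5% on noisy data, and at SNR 30 with four time points the
  median bias stays below 3% for $\tau$ between 10 and 120 ms when the time
  axis suits the tissue (TE up to ~15 ms for short-$\tau$, TSL up to ~80 ms
  for long-$\tau$ — as the respective sequences provide).

Regional biomarkers are arithmetic means over *valid* voxels only
(`map_region_mean()`); a region with no valid voxel yields an explicit
missing flag, and the unit is later excluded as `empty_region`.

## Fat fraction

`compute_bmff()` forms the signal fat fraction $100 \cdot F/(F+W)$ from
co-registered magnitude fat and water images. Full water-fat decomposition
(field map, $R_2^*$ correction) is an upstream reconstruction step; this
module consumes its outputs, in whatever convention the supplied images
carry. Voxels whose total signal falls below a floor (default $10^{-6}$ of
the image maximum) are invalid, and a slice-window parameter restricts the
analysis to a configurable number of central sagittal slices (five, by
convention, for mid-sagittal vertebral analysis).

## Geometry: standard frames and sub-regions

Tissue masks are standardised by their principal axes
(`principal_axis_frame()`): eigenvectors of the voxel-coordinate covariance
in mm, ordered by descending eigenvalue, signs fixed so each axis points
along its nearest scanner axis, rows ordered (AP, LR, SI). Conventions that
had to be fixed once:

* World coordinates come from the voxel grid and spacing with the origin at
  the grid centre; axis 1 = AP, axis 2 = LR, axis 3 = SI; the B0 axis is
  the scanner SI axis (supine acquisition).
* Near-isotropic or rank-deficient shapes (relative eigenvalue gap below
  5%) raise a degeneracy error naming the offending axes rather than
  returning an arbitrary frame.
* If the sign convention produces determinant −1, the weakest axis is
  flipped, preferring a proper rotation.
* Mapping principal axes to anatomy from scanner axes presumes the subject
  is roughly aligned with the scanner; it is reliable for tilts well below
  45°, and the rotation-invariance checks exercise perturbations up to 25°,
  a generous bound for supine positioning.
* After rotation, labels are resampled nearest-neighbour (no label mixing)
  and intensity maps trilinearly.

Three sub-regions reproduce the anatomical reading conventions:

* **Central CEP** (`central_cep_template()`): the CEP footprint — the
  projection of the sheet along its thinnest principal axis — intersected
  with a parametric *kidney-bean* contour: an ellipse matched to the
  footprint extents and scaled to `area_fraction` (default 0.5) of the
  footprint area, minus a posterior concavity lobe of relative depth
  `concavity_depth` (default 0.25) that carves the bean's indentation where
  the NP bulges. The exact template of the original segmentation tooling is
  not published, so this family is parametric and fully configurable; what
  matters downstream (and what the tests pin) is the configured area
  fraction, the containment in the CEP, and rotation covariance. The
  footprint deliberately uses the sheet's own axes rather than the
  anatomy-labelled frame: a CEP near the magic angle lies at ~45° between
  the scanner AP and SI axes, where an anatomy-based projection flips
  between orientations while the eigen-axes follow the sheet.
* **Hemi-vertebra** (`hemi_vertebra()`): split of the vertebral body at its
  centroid perpendicular to the SI principal axis; the superior half
  adjoins the superior endplate. The halves partition the parent mask
  exactly.
* **Central NP** (`np_central_region()`): voxels within the central 40%
  (configurable) of the disc's AP extent, optionally halved at the disc
  centroid to isolate the sub-region adjacent to a named endplate.

**Magic-angle filter.** Collagen's dipolar coupling term
$3\cos^2\theta - 1$ vanishes at $\theta = \arccos(1/\sqrt{3}) = 54.7°$;
away from it, CEP T2\* is artifactually depressed. `cep_angle()` measures
the CEP orientation as the total-least-squares line through the voxel
centres projected on the mid-sagittal plane, against the B0 axis, folded
into [0, 90]°. Endplates outside `magic_angle_window()` — ±15° about the
exact constant, both ends inclusive (the boundary convention had to be
chosen; inclusive is the permissive reading) — are excluded.

## Units, exclusions and reliability

`assemble_units()` joins the three regional biomarkers per endplate (4 per
subject: superior/inferior at L4/5 and L5/S1) with subject covariates. A
unit is included iff the subject has no CEP damage (damage precludes
segmentation, so it acts at the subject level), its angle is in the window,
and all three biomarkers are present; `exclusion_reason` records the first
failing rule (damage > orientation > empty_region). `apply_exclusions()`
emits a ledger whose arithmetic identity — final endplates = (complete
subjects − damaged) × 4 − orientation-excluded − empty — is asserted on
every call and property-tested under random exclusion patterns.

Intra-rater reliability of repeated segmentations uses the single-measure
intraclass correlation from the two-way ANOVA mean squares
(`intra_rater_icc()`). The absolute-agreement random-effects form ICC(2,1)
is the default — appropriate when the re-segmentation sessions are
exchangeable "raters" — with ICC(1,1) and ICC(3,1) available; the form used
by the original annotators is not recorded, which is why it is switchable.
The closed forms are verified against the classic six-target four-judge
benchmark table and against `aov` mean squares.

## Statistical models

With per-endplate units in hand (`stats` module):

* `univariate_ols()` — simple regressions of NP T1ρ on CEP T2\* or BMFF;
* `correlation_matrix()` — pairwise Pearson r with two-sided p-values;
* `pfirrmann_model()` — proportional-odds (cumulative logit) regression of
  the ordinal Pfirrmann grade on NP T1ρ by default, with a binary
  (grade ≥ III) logistic fallback; "logistic regression" against an ordinal
  grade is ambiguous, and proportional odds is the canonical ordinal
  reading;
* `mixed_model()` — the two multivariable models, REML via `lme4`, with a
  random intercept per subject for the repeated levels. `model1`: CEP T2\*,
  level, CEP T2\*×level, age, BMFF, sex, BMI. `model2`: level, CEP T2\*,
  CEP T2\*×level, age, BMFF, BMFF×level, CEP T2\*×BMFF, and the three-way
  interaction.

Coding conventions, chosen once and documented because the original
analysis software's defaults are not recorded: spinal level is effect-coded
(+1 = L4/5, −1 = L5/S1), so the level coefficient is half the L4/5−L5/S1
difference — consistent with a ~5.8 ms coefficient alongside a ~11.6 ms
level gap; sex is effect-coded (+1 = female); continuous predictors are
centred at their sample means before interactions are formed, making main
effects interpretable at the cohort mean (both switchable). Inference uses
Wald z intervals by default with Satterthwaite degrees of freedom as an
option (`lmerTest`); no multiplicity correction is applied, matching the
two-sided α = 0.05 convention of the analysis this mirrors.
Non-convergence is flagged on the result, never silently repaired.
`level_means()` returns model-adjusted per-level NP T1ρ means with 95% CIs
via `emmeans`.

`estimate_composition()` maps CEP T2\* to GAG content, water content and
collagen-to-GAG ratio through user-supplied affine calibrations
(`calibration_set()`). No coefficients are built in: they belong to
external ex vivo regression studies, and hard-coding them here would be
inventing data. Values outside the calibration's stated T2\* range are
flagged extrapolated; `subgroup_ranges()` reports per-analyte ranges within
covariate subgroups, which nest inside the full-cohort ranges by
construction.

## Synthetic data: what it emulates, and what it does not

**Phantom** (`generate_phantom()`): a vertebral box, an elliptical disc and
a thin CEP sheet tilted at a configurable angle (default 54.7°) are
voxelised analytically — membership is evaluated in the rotated frame, so
an applied rigid rotation produces a genuinely re-oriented phantom rather
than a resampled one. Signals follow the exact mono-exponential model with
per-tissue $\tau$ and $S_0$; fat/water images satisfy $F/(F+W)$ = the BMFF
truth; an optional superior-inferior BMFF gradient (e.g. 40→60%) gives the
hemi-vertebral split analytically known half-means (45% and 55%). Noise is
additive Gaussian by default with a Rician magnitude option; the Gaussian
suffices at the SNRs exercised (≥ 30), where the Rician bias is
negligible. Fixed seeds make outputs bit-identical.

**Cohort** (`generate_cohort()`): per-endplate NP T1ρ follows
$y = X\beta + b_i + \varepsilon$, with the default coefficients set to the
multivariable estimates the pipeline is meant to recover (CEP T2\* 1.06,
level 5.80, CEP×level 0.83, age −0.45, BMFF −0.13, sex 2.32, BMI −0.26
ms per unit; intercept 62.4 ms). Covariates come from a Gaussian copula
with truncated-normal marginals: age 40 ± 11.9 (19–65) years, BMI
26.1 ± 4.7 (18.8–45.7) kg/m², 47% female, and pairwise Pearson targets
(age-BMFF 0.599, BMI-CEP T2\* 0.339, ...). Two numerical refinements keep
the realised moments on target: the truncated-normal parameters are solved
so the *post-truncation* mean and SD equal the requested ones, and the
latent correlations are de-attenuated by each margin's linear Hermite
coefficient so the *output* Pearson correlations match their targets
(plain copula sampling would miss, e.g., 0.599 by several hundredths).
Values the source tables do not provide are stated here as this package's
assumptions, chosen once: BMFF 40 ± 10%, CEP T2\* 20 ± 5 ms, random
intercept SD 10 ms and residual SD 11 ms (so the implied total NP T1ρ SD
is ≈ 18 ms, the observed cohort figure), and Pfirrmann cutpoints
(85.5, 61, 48, 20 ms on the level-mean T1ρ plus 5 ms latent noise) that
reproduce the observed grade distribution (≈10/43/25/22% for I–IV, grade V
absent). Relaxation times are floored at 1 ms — a physical positivity
constraint clipping ~5×10⁻⁴ of draws at the defaults. Exclusions mirror
the study bookkeeping: subject-level damage probability 0.25 (20/80) and
endplate-level orientation-exclusion probability 110/240. CEP T2\* and BMFF
are drawn per endplate, conditionally on the subject's age and BMI, so all
pairwise correlation targets hold at the endplate grain while within-
subject similarity arises through the shared covariates.

What the generators do **not** emulate: realistic spine anatomy or
curvature, pulse-sequence physics, k-space or motion artifacts, partial
volume at tissue interfaces, spatially correlated noise, or measurement
error in the covariates. Passing tests therefore demonstrate the
correctness of the estimators and the internal consistency of the pipeline
under its own assumptions — not robustness to every property of clinical
data.

## Parameter recovery and error rates

`recovery_study()` simulates many cohorts, refits the mixed model, and
reports per-coefficient mean estimate, relative bias, Monte-Carlo SE, 95%
CI coverage and the α = 0.05 rejection rate. Coverage is judged against the
*per-replicate estimand*: the generative mean function projected onto the
fitted (sample-centred) design. Sample-mean centring is an exact
reparameterisation, so this equals the generative coefficient for every
term not involved in an interaction; for a term that is — the level main
effect under a CEP×level interaction — the fitted coefficient's true value
shifts by $\beta_{int}(\bar{x} - \mu)$, and judging its CI against the
unshifted population value would report spurious undercoverage (~87% where
the interval's own estimand is covered at ~95%).

Problem sizes, chosen to make Monte-Carlo error small against the
tolerances they support: 200 cohorts × 500 subjects for bias/coverage
(relative bias within 5% for the headline coefficients; coverage within
[92%, 98%]), and 1000 cohorts × 60 subjects with the CEP effect zeroed for
the type-I error of its Wald test (within [3%, 7%]). The acceptance script
(`scripts/acceptance.R`) re-runs these studies from scratch along with the
bookkeeping, relaxometry, geometry and ICC checks, and writes the resulting
quantities as JSON.

## Known limitations

* The kidney-bean template is a parametric stand-in for an unpublished
  template; only its configured area fraction and invariances are
  meaningful, not its exact contour.
* The anatomy labelling of principal axes assumes near-supine orientation
  (tilts ≲ 25–30° are safe; 45° is the geometric breaking point).
* Wald z inference is mildly liberal at small subject counts (the type-I
  study at n = 60 sits near 5–6%); Satterthwaite df via `lmerTest` is the
  conservative alternative.
* The composition module is an interface: without a user-supplied
  calibration it deliberately refuses to produce numbers.
* Voxel-level Dice comparisons of thin (≈2 voxel) structures are limited by
  nearest-neighbour resampling itself, not by the region extractors; the
  rotation-covariance checks therefore use either analytic re-voxelisation
  or thicker slabs.
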