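---
title: "Voxel-wise population QA for synthetic CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise population QA for synthetic CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sctqa)
```

## The problem

MRI-only radiotherapy planning replaces the planning CT with a synthetic CT
(sCT) generated from MRI. Before an sCT generation method can be trusted
clinically, its errors — in Hounsfield units and, more importantly, in the
dose computed from it — must be characterized. Global scores (one MAE per
patient) hide *where* a method fails. `sctqa` implements a population-based,
voxel-wise QA workflow: every patient's images, structures, doses and error
maps are brought to one common coordinate system (CCS) by an organ-driven
deformable registration, and per-voxel statistics across the cohort (mean
error maps, a paired permutation test, cumulative dose-error histograms,
DVH criteria and a 3D gamma analysis) localize and quantify the differences
between sCT methods.

Because clinical imaging data cannot ship with a package, `sctqa` includes a
fully synthetic pelvic phantom cohort generator. The phantom is a first-class,
tested component: it defines the study conditions under which every stage of
the workflow is exercised end to end.

## The phantom cohort

Each patient is built from analytic primitives on a regular grid (defaults
96 x 96 x 48 voxels at 2 mm): an elliptical body; two femoral heads and a
sacrum, each split into a dense cortical shell (650 +/- 120 HU) around a
spongy interior (100 +/- 80 HU), emulating the strong heterogeneity of real
bone; a bladder; a prostate with two seminal-vesicle blobs fused to it
(CTV1 = prostate + vesicles, CTV2 = prostate, mirroring a sequential
50 Gy + 28 Gy prescription); and a gently curved rectal tube containing an
air pocket (-700 +/- 50 HU). Soft tissue sits near 0 HU (30 +/- 20). The
MRI-like volume uses a different, T2-flavored monotone intensity map
(bladder bright, bone dark), a smooth multiplicative bias field (8%
amplitude, 40 mm correlation) and additive noise, clamped at zero as a
magnitude image.

Inter-patient variability combines (i) a global anisotropic scale per
patient (SD 6% per axis), (ii) per-organ scale (SD 5%) and position jitter
(SD 3 mm), and (iii) a smooth random warp of the whole anatomy (2.5 mm
amplitude, 25 mm correlation) applied analytically to the primitive
coordinates, so the exact displacement field is retained as ground truth for
registration tests. These values were chosen once as a plausible caricature
of inter-patient pelvic variability: organ volume coefficients of variation
around 20-30% and organ displacements of a few millimetres up to about a
centimetre, comparable to the spread reported for clinical cohorts. Every
draw is keyed to a per-patient seed derived deterministically from the
cohort seed, so a cohort is fully reproducible.

What the phantom does *not* emulate: MR physics (susceptibility, distortion),
Hounsfield calibration subtleties, pathology, weight change between scans,
or delineation error. Consequences for interpretation are discussed at the
end.

### The two sCT methods under comparison

* **Bulk density**: air is segmented inside the rectum by thresholding the
  MRI below 0.3 x the median body intensity (the threshold is a package
  default; it is exposed in the configuration because real protocols
  calibrate it), then a piecewise-constant image is assembled with
  0 HU (soft tissue), 350 HU (bone), -450 HU (air) and -1000 HU outside the
  body. Precedence on overlap is air > bone > soft.
* **Learned-like**: the reference CT plus a smooth, spatially correlated
  error field with per-tissue amplitude (defaults: soft 25, bone 90, air
  60 HU; correlation 12 mm), standing in for the residual error pattern of
  a trained image-translation model. The white-noise field is smoothed with
  a unit-sum Gaussian kernel, so the realized error SD is the amplitude
  times the kernel variance-shrink factor `sqrt(sum(k^2))` per axis; with
  the default correlation length the realized errors are a few HU — a
  deliberately *low-error* method, so the workflow's job is to rank it
  clearly above the bulk method.

## The dose surrogate

A treatment planning system is out of scope, but dose QA needs a dose engine
whose output responds to HU errors. `compute_dose()` casts parallel rays for
each of 7 coplanar, equally spaced beams aimed at the target centroid. Each
beam deposits `w * P(lateral) * exp(-mu * integral of rho_e dl)`, where
`rho_e(HU)` is a piecewise-linear relative-electron-density calibration
through (-1000, 0), (0, 1), (1000, 1.6), `mu = 0.005/mm` per unit density,
and `P` is a sigmoid lateral field edge (3 mm penumbra) with the field
radius set by the target extent plus a 5 mm margin. Beam weights are
calibrated **once on the reference CT** — plan 1 scaled so the median CTV1
dose is 50 Gy, plan 2 so the median total CTV2 dose is 78 Gy (a
deterministic one-dimensional root find) — and reused verbatim on every
sCT, so image errors propagate into dose errors exactly as a fixed clinical
plan would. There is no scatter, no MLC modeling and no absolute dosimetry:
only the *error-propagation* property matters for the QA pipeline, and on a
homogeneous phantom a single beam reproduces the closed-form exponential
depth profile to within 1e-6.

## Native-space error metrics

For each patient, `voxel_errors()` computes the signed error
`e = ref - pred` (positive where the sCT underestimates), `ae = |e|` and the
absolute percent error `ape = |e / ref|`. Division by the reference is
undefined where it crosses zero, so APE carries a validity mask: |ref| must
exceed 1 HU (or 0.01 Gy for doses), and regional MAPE averages only valid
voxels. The sign convention and the unguarded shape of the percent error
reproduce a known artifact faithfully: a bulk sCT with 0 HU soft tissue has
APE identically 1 across soft tissue, and the statistics report it as such
rather than hiding it.

## Organ-driven registration to the CCS

The template is the patient whose bladder, rectum and prostate volumes are
jointly closest to the cohort medians (summed relative deviation; ties to
the lowest id). Every other case is registered to it through a staged
pipeline; all stages accumulate into a single composed displacement field
(backward warping, mm units), and all volumes are propagated with exactly
one resampling from native space.

**Structural description.** Each organ gets an interior scalar profile:
the solution of the discrete Laplace equation inside the mask with value 1
on the surface and 0 on a sink — the slice-wise central path for the
tubular rectum, the barycenter for the prostate — and a signed-distance
depth ramp for body, bones and bladder. Profiles are affinely rescaled into
disjoint intensity bands (body 0.05-0.15, bones 0.2-0.35, rectum 0.4-0.55,
prostate 0.6-0.75, bladder 0.8-0.95) and summed. Because the organ masks
are disjoint, the bands do not overlap spatially: every organ surface
carries its own sharp, unambiguous contrast step, and **all stages optimize
one consistent image**, which is what keeps a later stage from pulling an
already-aligned neighbour toward a conflicting optimum. The merged
description alpha-blends this banded sum with the intensity-normalized MRI
(weight 0.5) and drives the whole-pelvis stage and the rigid prealignment.

**Pipeline.** (i) translation-only rigid alignment: body centers of mass
plus a local mean-squared refinement (+/- 5 mm, 1 mm steps, on 4x
downsampled merged descriptions); (ii) a coarse free-form prealignment on
the bladder profile (control-point spacing 16 voxels, trilinear control
interpolation, mean-squared metric, normalized-gradient descent);
(iii) a smooth Gaussian-RBF landmark field (sigma 30 mm) interpolating the
residual centroid offsets of the bladder, the prostate, three sections of
the rectal tube and each connected bone component, anchored by
zero-displacement landmarks at the body extremes — one smooth warp that
brings every organ within the capture range of the intensity stages;
(iv) staged multi-resolution Demons in the order bladder, whole pelvis,
prostate, rectum, bones, with the iteration schedule
(300,300,200,20), (200,200,100,0), (200,200,150,5), (100,100,100,5),
(100,100,150,50) over four resolution levels and Gaussian regularization
sigma 1 (voxels; the finest grids here are coarser than clinical voxels, so
the four levels use downsample factors 4, 2, 1, 1 rather than 8, 4, 2, 1 —
at 2-2.5 mm spacing a factor-8 level would reduce the prostate to a single
voxel). Each organ stage is driven by its own band plus the body background
and the bands of organs aligned by earlier stages (an aligned organ sits in
force equilibrium and keeps its position; organs not yet aligned are left
out so they cannot attract the stage organ into a wrong basin), is
initialized by a local centroid snap, and applies its displacement delta
only within 10 mm of its organ. The whole-pelvis stage aligns the body
outline and soft tissue globally; the bones stage freezes the soft organs
(zero delta out to 3 mm off their surfaces, ramp to 4 mm further) so its
large corrections cannot drag them.

**Demons numerics.** Symmetric forces
`u = -(diff) * g / (|g|^2 + diff^2 / s^2)` with `g` the mean gradient of
fixed and warped-moving images, a per-iteration step cap `s` of one
full-resolution voxel at *every* level (coarse levels moving at
coarse-voxel strides destabilize the accumulation), Gaussian smoothing of
the update field (sigma 1 voxel) and a diffusion-like smoothing of the
stage's accumulated delta, annealed across the resolution levels
(0.75, 0.5, 0.25, 0.25 voxels): strong coarse-level regularization moves
whole organs coherently and avoids partial-lock local minima, while the
weak finest-level smoothing lets the surfaces converge to sub-voxel
agreement (stronger smoothing there leaves an equilibrium boundary offset
that keeps registered organ volumes from contracting). A localized stage's
masked delta receives one extra light smoothing pass (sigma 0.5 voxel)
because masking a smooth field can fold space at the weight boundary, and
the local centroid snaps widen their falloff to 1.5x the snapped offset so
the implied weight gradient stays below 2/3. Accumulation is compositive
`f <- u + f(x + u)`. Each stage estimates a fresh delta on the
init-warped moving image and composes it afterwards: resampling the full
accumulated field through a stage's coarse pyramid would erase the fine
detail gained by earlier stages.

**Validation and gating.** Per-organ Dice coefficients against the template
structures gate each case: all five organs must exceed 0.85 *strictly*, or
the case is excluded from the population statistics. The fraction of
positive Jacobian determinants of `id + f` inside the body tracks the
diffeomorphic intent (>= 99% required in the acceptance checks). After
propagation, the bones of the warped CT and of the template CT are each
split into cortical and spongy compartments by Otsu thresholding inside the
bones mask, and one extra Demons stage per compartment (driven by a
two-band compartment image, localized to the bones, soft organs frozen) is
composed on. The refined field is kept only when it degrades no organ's
Dice (a bone-only improvement with at most 0.005 loss elsewhere is also
accepted), and the refinement is skipped with a warning when the split is
degenerate (one compartment under 5% of the bone volume).

## Population statistics in the CCS

With p patients aligned, each voxel i carries paired values
(ref(i,j), pred(i,j)), j = 1..p, restricted to the template body contour:

* `vMAE(i) = mean_j |ref - pred|`, `vME(i) = mean_j (ref - pred)`,
  `vMAPE(i)` averaged over valid patients only;
* `RSD_AE(i) = sqrt(mean_j (AE - vMAE)^2) / vMAE`, the coefficient of
  variation of the absolute error — the per-voxel uncertainty of the
  method. It is implemented as a proper coefficient of variation
  (population variance, square root, normalized by the mean), which is what
  the name demands even where abbreviated notations elsewhere drop the root
  and the 1/p factor; it is undefined (NA) where vMAE is below the APE
  epsilon.

**Permutation test.** At each voxel the studentized statistic
`T = mean(D) / (sd(D)/sqrt(p))` (sample SD) is compared with its
distribution under `n_perm` independent random sign-flip vectors — swapping
a pair (ref, pred) is exactly a sign flip of its difference, which is the
correct exchangeability null for paired data. Implementation choices, all
documented because conventions differ between tools:

* the two-sided p-value uses the add-one estimator
  `(1 + #{|T*| >= |T|}) / (n_perm + 1)`, so p is never exactly zero;
* voxels with all differences zero carry no evidence and get p = 1;
* constant non-zero differences give |T| = Inf; only all-same-sign flip
  vectors tie, so the p-value concentrates near `2^(1-p)`;
* one flip matrix (from the seed) is shared across voxels. Marginal
  p-values are unaffected by this choice; it preserves the spatial
  coherence of the null and allows the statistic to be computed as a single
  matrix product per block of voxels;
* no multiple-testing correction is applied beyond the permutation scheme
  itself; the error subregions (ESR) are simply `{p < alpha}` with a strict
  inequality at alpha = 0.05.

## Dose QA

* **MADE-VH**: the cumulative histogram of the voxel-wise mean absolute
  dose error — for each threshold, the percent of an ROI's volume with
  vMAE at or above it (non-increasing, 100% at 0). `V(0.5 Gy)` and
  `V(1 Gy)` summarize it. The pelvis ROI is the body cropped to 2 cm above
  and below the rectum along the superior-inferior axis; organ ROIs are
  used uncropped.
* **DVH criteria**: Dmean and Dx% for x in {2, 50, 95}, with Dx% the
  (100-x)th percentile of the in-ROI dose by linear interpolation of the
  order statistics (R's type-7 quantile); differences are reported as
  absolute values per ROI, computed on the mean CCS doses.
* **3D gamma** (local, 1%/1 mm, 10% low-dose threshold by default) on the
  mean reference dose vs the mean method dose in the CCS. The search is
  truncated at 3x the DTA (values beyond are capped, standard practice),
  with trilinear subvoxel sampling on a lattice at least 3x finer than the
  voxel grid and 10x finer than the DTA — the gamma optimum is quadratic
  around its argmin, so the lattice must be well below the DTA scale for
  the index to converge. The pass criterion is gamma <= 1; an exact tie at
  1 is measure-zero and counted as a pass.

## Numerical choices and degenerate inputs

* Geometry comparisons use an absolute tolerance of 1e-6 mm; mixed-unit
  arithmetic raises an error (HU/Gy mix-ups are caught, not silently
  propagated).
* Laplace solves use Gauss-Seidel iteration to a maximum update below 1e-5;
  out-of-mask neighbours take the surface value. Disconnected masks are
  rejected (26-connectivity, appropriate for thin digital tubes); a
  centroid or barycenter falling outside the mask is snapped to the nearest
  in-mask voxel with a warning.
* Distance maps are exact anisotropic Euclidean transforms
  (voxel-center convention: positive outside to the nearest mask voxel,
  negative inside to the nearest background voxel).
* Out-of-field warping fills -1000 HU, 0 Gy or 0 depending on the unit tag;
  masks always warp nearest-neighbour and stay binary.
* Dice of two empty masks is defined as 1 (vacuous agreement).
* The phantom regenerates a patient's jitter (up to 10 times) when a drawn
  configuration pushes organs outside the body or lets bone precedence
  disrupt the rectal tube.

## Problem sizes

The test suite and the acceptance script run the full workflow on a
10-patient cohort at 64 x 64 x 32 voxels and 2.5 mm spacing — the smallest
grid that holds the default anatomy with organs a handful of voxels across,
chosen so statistical behavior is measurable while a complete run stays in
the minutes range. Permutation-test calibration uses 26 patients of iid
differences on a 20 x 20 x 5 grid with 2000 permutations; oracle-equivalence
checks use 16^3 to 24^3 grids. Production-scale use (the 2 mm default grid,
10,000 permutations) only changes run time.

## What the tests do and do not show

Green tests demonstrate that the statistical machinery is calibrated (type-I
error at nominal level, super-uniform p-values, near-complete power at a
three-sigma shift), that every metric agrees with independent brute-force
oracles, that the registration pipeline reaches the Dice gate on anatomies
with known ground truth, and that the end-to-end workflow correctly ranks a
low-error sCT method above the bulk method in every reported quantity. They
do not demonstrate performance on clinical images: real MRI contrast,
delineation noise, and anatomy changes between scans (rectal filling, bladder
volume) are outside the phantom's scope, and the registration — the
best-understood failure mode of any voxel-wise population analysis — must be
re-validated with the Dice gate whenever the workflow is applied to real
cohorts.
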