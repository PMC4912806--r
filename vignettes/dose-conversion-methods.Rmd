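---
title: "Modeling pencil-beam to Monte Carlo target dose conversion"
author: "sbrtDoseConv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pencil-beam to Monte Carlo target dose conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrtDoseConv)
```

## The modeling problem

Type-A dose algorithms such as pencil beam (PB) overestimate target
coverage in lung SBRT because they mishandle lateral charged-particle
transport where a dense tumour meets low-density lung. Recalculating a
PB plan with Monte Carlo (MC) lowers the target dose by an amount that
varies strongly between patients. The quantity this package models is
the percent PTV D95 deficiency,

$$\%\mathrm{diff}_{PTV\,D95} = 100\,\frac{D95_{PB} - D95_{MC}}{D95_{PB}},$$

with the PB value as denominator: for a plan normalised so that 95 % of
the PTV receives the prescription, the PB PTV D95 *is* the prescription,
and the deficiency reads as a percentage of prescribed dose.

The modeling idea is to replace the coarse central/peripheral location
dichotomy with continuous, quantifiable features. Mean Hounsfield units
(HU) of structures around the target act as density surrogates: a PTV
surrounded by pure lung (low shell HU) poses a harder transport problem
than one abutting the chest wall, and should suffer a larger deficiency.
The feature set is

* size — PTV and GTV volumes (cm³) and the maximum GTV dimension MaxD
  (mm);
* location — mean HU of PTV, GTV, PTV margin (PTV minus GTV), and
  2/15/50 mm shells immediately outside the PTV, plus the minimum
  distance from the GTV to soft tissue, `dmin` (mm);
* lung density — mean HU of the whole lungs (tumour not excluded);
* secondary indices — the HU standard deviations of the same seven
  structures.

The 15 mm shell corresponds to the depth of maximum dose of 6 MV
photons; the 2 mm shell to a typical initial MLC block margin; the 50 mm
shell to a broad surrounding region. GTV density is carried along but is
exploratory: tumour density is pathology- more than location-dependent.

Three model families consume the features: a per-feature single linear
regression screen ranked by R²; multiple linear regression with the
whole-model F-test P value reported as the *significance factor*,
including two fixed published coefficient sets (`eq1` with the PTV
volume, `eq2` with its 2/3 power — a surface-area surrogate, since the
interface area is what drives the transport error); and a
single-hidden-layer feed-forward network.

## Geometry: physical-distance operators

All expansions, shells and distance indices use an exact Euclidean
distance transform (separable lower-envelope algorithm, implemented in
C++) that works in millimetres on the per-axis voxel spacing. This
matters because CT grids are anisotropic: a "2 mm shell" is a physical
statement, not a voxel count. Masks are voxel-centre membership sets
with no partial-volume weighting, matching first-order TPS behaviour.
The coordinate convention is 0-based indices with world position =
index × spacing.

Numerical conventions:

* `expandMask` includes voxels at distance exactly equal to the margin
  (a 1e-9 mm tolerance absorbs floating-point noise).
* `dminGtv` measures voxel-centre distances from the GTV and excludes
  GTV voxels from the soft-tissue set. Any centre distance within one
  voxel diagonal is reported as 0 mm: face/edge/corner contact *is*
  abutment at voxel resolution. Accuracy is therefore one voxel
  diagonal, which the tests assert against a brute-force pairwise
  oracle.
* `maxDiameter` computes the exact pairwise maximum over surface voxels
  only (erosion by the 6-neighbourhood), which cannot change the
  maximum.
* The soft-tissue threshold for `dmin` defaults to −200 HU, separating
  lung parenchyma (≈ −900…−500 HU) from chest wall and mediastinum. The
  clinical definition is operational, so the threshold is an exposed
  parameter rather than a constant.
* HU standard deviations use the sample (n−1) denominator, conventional
  for cohort statistics and negligibly different at structure voxel
  counts.

## DVH metrics

`doseAtVolume(dose, mask, p)` returns the largest dose d such that at
least p % of the structure's voxels receive ≥ d — the lower
order statistic, which matches the verbal D95 definition exactly and is
checkable against an exhaustive threshold sweep. A linearly interpolated
variant sits behind `interpolate = TRUE`; the order-statistic form is
the default because the two differ by at most one DVH bin and only the
former is oracle-exact. Dose and CT must share a grid; no resampling is
performed inside the metrics.

## The synthetic phantom and dose pair

No patient data ship with the package, so a generator stands in for the
cohort, with defaults chosen once to represent a realistic thoracic
case:

* 90 × 90 × 60 voxels at 2 × 2 × 2.5 mm (anisotropic on purpose);
* an elliptic body section of soft tissue (30 ± 20 HU) containing two
  lung ellipsoids (−750 ± 50 HU), air at −1000 HU outside, all HU
  clipped to the physical CT range [−1000, 1500];
* a uniform spherical tumour (20 HU, default radius 10 mm) placed as an
  *island* (lung on all sides), against the *chest wall*, or against the
  *mediastinum*; wall/mediastinal tumours overshoot the lung boundary by
  one voxel so abutment (dmin = 0) holds at voxel resolution;
* GTV → ITV by a fixed 2 mm expansion (a stand-in for the respiratory
  envelope — motion is not simulated), ITV → PTV by the standard 6 mm
  uniform margin, PTV clipped to the body.

The paired dose grids emulate the spatial signature of the algorithm
difference rather than any beam model. The PB-like field is the
prescription inside the PTV plus a 3 mm plateau margin, a Gaussian
penumbra (σ = 4 mm) outside, and a mild central boost placing the
prescription near 90 % of the maximum dose; it is then renormalised so
the PTV D95 equals the prescription exactly. The MC-like field is
PB × (1 − δ·g), where g = 1 at and outside the PTV surface and decays
inward with a 5 mm length scale — underdosage concentrated at the
target periphery. The single amplitude δ is solved by bisection on
[0, 0.9] (40 iterations) so the realised percent PTV D95 deficiency
lands within 0.25 percent points of the request; an unreachable target
raises an error rather than returning the closest value. Because g is
small in the target centre, the Dmax deficiency is automatically much
smaller than the D95 deficiency, and MC ≤ PB holds voxelwise by
construction.

The cohort-table generator draws the PTV volume uniformly on
7.2–110.2 cm³ and the 2 mm-shell mean HU uniformly on −820…−350 HU,
then sets the outcome from a published model plus Gaussian noise
(default SD 2 percent points), clipped to [0, 40] as a physical guard.
With these defaults the noiseless predictions stay inside the printed
clinical range, so the clip almost never binds and the "noiseless
cohort refits the generating coefficients exactly" contract holds. A
uniform volume draw slightly overstates the typical cohort median (a
log-uniform draw would match a right-skewed clinical volume
distribution better) but is kept for its simple, documented contract.
Companion densities (PTV, margin, 15/50 mm shells, lung) are affine in
the shell density plus independent jitter, tuned to pairwise Pearson
r ≈ 0.8–0.95 — reproducing the collinearity that makes "adding a second
density feature hurts the multiple regression" demonstrable — while the
volume stays independent of all densities.

What the phantom does *not* emulate: respiratory motion and 4D-CT ITV
construction, beam/MLC geometry, heterogeneous tumour texture (the GTV
is uniform, so its HU standard deviation is degenerate and the screen
skips it with a warning), vessels and airways inside lung, and
realistic chest-wall thickness. Passing tests demonstrate the
pipeline's correctness and the qualitative feature ordering under these
conditions, not clinical performance on real cohorts.

## Regression and inference

`fitSingle`/`fitMultiple` are ordinary least squares via `stats::lm`,
reporting unadjusted R² (adjusted R² is carried but never used for
ranking), per-coefficient two-sided t-test P values, and the F-test P
value as the significance factor — the standard whole-model summary
consistent with the printed magnitudes for a 21-patient, two-feature
model. Degenerate inputs are explicit: a constant predictor errors; a
constant outcome returns R² = 0 with a warning; a rank-deficient design
errors naming the collinear columns. No multiple-testing correction is
applied across the feature screen (none is standard for an exploratory
ranking, and the screen is labelled exploratory).

The critical correlation helper inverts the t-test of zero correlation:
r* = t*/√(t*² + n − 2). The Mann-Whitney test uses the exact null
distribution when the smaller sample has ≤ 8 observations and no ties,
and the tie-corrected normal approximation otherwise; the tests verify
the exact branch against full enumeration and the agreement of the two
branches.

## The network regressor

`annTrain` wraps `nnet`: one logistic hidden layer, linear output,
all weights L2-penalised by the decay parameter, quasi-Newton
optimisation capped at 500 iterations (non-convergence is flagged on
the result, not thrown). Inputs are standardised on the training data;
the outcome is min-max normalised to [0, 1] on the training data, with
a zero-range guard mapping a constant outcome to 0.5. Weights
initialise uniformly in [−0.5, 0.5] from the seed, so every fit is
reproducible.

`annGridSearch` scans hidden sizes 2–7 × decays
{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1} by seeded 5-fold CV RMSE on the
normalized scale (5-fold is cheaper than nested LOOCV and standard
practice for a wrapper whose inner resampling is otherwise
unconstrained; the fold count rises automatically when n is so small
that a training fold would drop below the trainer's minimum). Ties
break toward the smaller size, then the smaller decay — parsimony.
`annLoocv` refits per held-out case with normalisation bounds
recomputed on each training fold only; the leakage contract is tested
white-box (each fold equals an independent retrain without that case).
Per-case squared errors on the normalized scale feed the Mann-Whitney
comparison against the linear model's LOOCV errors, computed on the
identical scale by `loocvLinear`.

## The study pipeline

`runStudy` orchestrates one of three input modes — phantom simulation,
a prepared feature table, or per-patient NIfTI grids — through the
screen, the two published model forms, a collinearity probe (the
two-feature model plus the PTV mean density), and the ANN comparison,
writing a manifest first and then CSV/JSON artefacts with fixed names.
The manifest plus seed fully determine every output; reruns are
byte-identical, which the tests assert. In phantom mode the assigned
deficiency of each phantom comes from the `eq2` predictor evaluated on
the phantom's own extracted features plus noise, and the *realised*
deficiency — recomputed from the paired dose grids through the DVH
code — is the modeled outcome, closing the loop through every module.

Problem sizes used throughout the tests and the acceptance script —
90 × 90 × 60 phantom grids, 21-phantom studies, 200-replicate
coefficient-recovery checks at n = 200 — were chosen as the smallest
sizes at which the constructions are voxel-resolution-clean and the
statistical contracts are stable.

## Known limitations

* The phantom's dose pair is a geometric emulation of the PB/MC
  difference, not a transport calculation; absolute deficiency
  magnitudes are inputs, not predictions.
* Published-model coefficients are plan-technique-specific (6 MV
  dynamic conformal arcs, ITV-based margins, ~90 % prescription
  isodose); applying them to other techniques changes the quantitative
  picture even though the methodology transfers.
* `dmin` is reported at voxel-diagonal resolution; sub-voxel surface
  geometry is out of scope.
* DICOM-RT import is not implemented; grids enter as NIfTI (or
  in-memory arrays), which keeps the I/O layer dependency-light.
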