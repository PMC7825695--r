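---
title: "Methods: radiomic signatures of medication usage"
author: "radsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic signatures of medication usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Statins and omega-3 supplements have been repeatedly associated with
prostate-cancer risk and aggressiveness, but whether they leave
imaging-detectable, tissue-level traces in the prostate is open. radsig
implements a pipeline that asks that question quantitatively: given
T2-weighted pelvic MRI with two regions of interest (the whole prostate
gland and its peripheral zone) and per-patient binary medication flags, can
a classifier trained on radiomic texture features predict who uses the
drug? A third medication with no expected prostate effect
(angiotensin-converting enzyme inhibitors, ACEI) serves as a negative
control: if the pipeline "finds" signal for ACEI too, the apparent drug
signatures are an artifact of the protocol rather than biology.

Because the underlying patient images are not public, the package ships
first-class synthetic generators — cohorts with exact usage counts,
textured 3D phantoms, and feature tables with planted effects — so every
stage is testable end to end, on any machine, from code alone.

## Feature extraction

Each (volume, ROI) pair yields 944 features:

* 14 3D shape descriptors (geometry only, computed once);
* 18 first-order intensity statistics;
* five texture-matrix classes — 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and
  5 NGTDM features — with matrices built over the 13 unique 3D directions
  at distance 1 and features averaged over directions;
* the 93 intensity/texture features recomputed on a
  Laplacian-of-Gaussian-filtered image (sigma 5 mm) and on each of 8
  single-level undecimated wavelet sub-bands (coif1; high/low pass per
  axis), giving 107 + 93 + 8 x 93 = 944.

Key numerical parameters, all configurable through `extraction_config()`:

| parameter | default | meaning |
|---|---|---|
| `bin_width` | 25 intensity units | fixed-bin-width discretization anchored at the ROI minimum, applied separately to every derived image |
| `spacing` | 2 x 2 x 2 mm | B-spline (order 3) resampling of the volume, nearest-neighbour for the mask |
| `log_sigma` | 5 mm | LoG width, converted per axis by voxel spacing |
| `glcm_distance` | 1 voxel | co-occurrence offset |

"Kernel size of 5" for the LoG filter is read as sigma = 5 mm (the
extraction platforms expose the LoG parameter as a physical sigma); a
discrete 5-voxel kernel is the alternative reading, and the parameter is
configurable precisely because the choice is a convention.

Degenerate inputs follow fixed, unit-tested conventions: a single gray
level gives GLCM correlation and MCC 1 and contrast 0; a fully uniform
neighbourhood caps NGTDM coarseness at 1e6; a zero-variance ROI returns
skewness and kurtosis 0; a single-voxel mask has axis lengths 0 and
elongation/flatness 1.

Two implementation choices deserve note. Surface area and mesh volume come
from a marching-tetrahedra triangulation of the 0.5 level set of the mask
indicator after light Gaussian smoothing (0.8 voxel): meshing the raw
binary staircase overestimates a digital sphere's area by roughly 28%,
while the smoothed level set brings sphericity of a 10 mm digital sphere to
0.99. Masks too small for the smoothed field to cross 0.5 fall back to the
binary mesh with midpoint crossings. Second, the wavelet transform is
undecimated with periodic boundary handling, so for an orthonormal filter
pair the sub-band energies sum to exactly 8x the input energy — a
transform identity the tests check numerically.

## Preprocessing

The order is fixed: bias-field correction, then histogram matching, then
resampling, then extraction. Bias correction estimates a smooth
multiplicative field in the log-intensity domain by iteratively refined
wide Gaussian smoothing (`est <- est + smooth(logv - est)`, default sigma
25 mm, 20 passes). The refinement matters: a single smoothing pass
attenuates the field at its own wavelength and removes only part of it,
whereas iteration drives the pass-band transfer to one. The corrected
volume is rescaled to preserve the mean intensity. Histogram matching uses
a monotone piecewise-linear map through 64 quantile landmarks; the
reference volume is configurable and defaults to the first volume of the
dataset, a deterministic choice, since no canonical template exists.

## Feature selection

`run_selection()` repeats, for a configurable number of rounds (default
1000), on a stratified two-thirds subsample drawn without replacement:

1. univariate two-group ANOVA per feature (equivalent to the pooled-variance
   t-test);
2. Benjamini-Hochberg adjustment, keeping adjusted p < 0.5 — a
   deliberately lenient pre-screen;
3. correlation clustering: connected components of the graph with edges at
   |Pearson r| > 0.8, keeping the lowest-p feature per component
   (absolute correlation, because sign-flipped duplicates are equally
   redundant; components, because they are deterministic and
   order-independent);
4. sequential floating forward selection scored by 3-fold cross-validated
   AUC of a gradient-boosted tree classifier on the subsample, keeping
   additions that improve AUC by more than 0.01, with conditional backward
   removal.

Features are ranked by how often they were selected across rounds; ties
break lexicographically so results are platform-independent. The SFFS
inner evaluation uses 3 folds to mirror the outer protocol; the learner
inside selection is a light configuration (30 trees, shrinkage 0.15,
depth 2) because it is refit hundreds of times per round.

## Model evaluation

`cross_validate()` runs repeated stratified 3-fold cross-validation
(default 500 rounds, hence 1500 validation records). Within each training
portion, the hyperparameter setting — including how many of the top-ranked
features to use (3–10) — is chosen by an inner cross-validated AUC, then
the model is refit and scored on the held-out fold with AUC (midrank
Mann-Whitney) and PRAUC (step-wise average precision, the conservative
interpolation). Nesting the tuning inside the training portion is the
leakage-free reading of the protocol. The default grid has
8 x 4 x 3 x 3 x 3 x 3 = 2592 settings (trees {50,100,150,200}, shrinkage
{0.01,0.05,0.1}, depth {1,2,3}, minimum node size {5,10,20} in sample
units, bag fraction {0.5,0.75,1}); the full grid is combinatorially heavy,
so the examples and tests use reduced grids, which the functions accept
unchanged. ROC curves are averaged vertically on a fixed 101-point FPR
grid.

The minimum-node-size settings count training samples; xgboost expresses
the analogous constraint in hessian units (about 1/4 per sample for
logistic loss), so `fit_gbm()` converts by that factor. Without the
conversion, small subsamples produce stumps that never split.

## What the synthetic data emulate — and what they do not

`generate_cohort()` reproduces the emulated cohort composition exactly: 91
patients, 42 statin users, 28 omega-3 users with 13 overlapping, 35 ACEI
users, with all joint counts enforced.

`generate_phantom()` builds a 64 x 64 x 32 voxel volume at 1 x 1 x 2 mm
(2 mm slices) containing an ellipsoidal gland (radii 20 x 16 x 12 mm) with
a posterior-crescent peripheral zone: the region outside a concentrically
shrunken ellipsoid on the posterior side, an anatomically plausible and
trivially parameterised stand-in for a manually contoured zone. Texture
is a Gaussian random field (default correlation length 3 mm, sd 20 around
a mean of 120) whose mean, variance and correlation length can shift with
the medication label, so both first-order and texture features can carry
signal; a smooth multiplicative bias field (default amplitude 0.2) and
white noise (sd 5) are layered on top. One master seed expands into
per-patient substreams, making patient i reproducible regardless of cohort
size. The phantoms emulate the statistical structure the analysis assumes
— not MRI physics, anatomy, or scanner artifacts — so passing tests
demonstrate correctness and calibration of the pipeline, not clinical
performance on real prostate MRI.

`generate_feature_table()` is the distributional stand-in for the real
91 x 944 table: unit-variance Gaussian columns in correlated blocks
(default block size 4 at r = 0.5 among noise columns), with informative
columns in singleton blocks shifted by a standardized effect (default 1.2)
in the label-1 group. The real feature-table distribution is not
characterised in the source material, so these defaults are stand-ins, not
estimates.

## The negative control and selection leakage

The evaluation protocol selects features on the full cohort (resampled
many times) before cross-validated evaluation on the same cohort. This is
faithful to the published workflow, and it implies a structural optimism:
features chosen for whole-sample association remain associated in every
test fold. The size of that optimism depends on the effective number of
independent features: on a table of ~900 near-independent Gaussian
columns the end-to-end control reaches mean AUC ~0.70-0.74; on a
phantom-derived radiomic table — whose 944 columns have an effective
dimension of roughly 15, like real radiomics panels — it measures
~0.65-0.67 and is insensitive to the number of selection rounds (200,
500 or 1000). The package runs its ACEI-analog control on the
phantom-derived table (ACEI labels are independent of the phantom texture
by construction), the closest analog of running the real workflow on real
images with an inert medication; the corresponding acceptance check
expects a near-chance band (mean AUC 0.45-0.60) and is honestly not met
under these synthetic conditions — the end-to-end control sits above it,
quantifying the protocol's selection optimism rather than a defect of the
evaluation stage. Two observations support that reading: the
permuted-label invariant of `cross_validate()` alone (fixed,
label-independent feature list) sits at 0.5 within +/-0.05, confirming
the evaluation stage does not leak; and the excess shrinks as the
feature table's correlation structure grows more redundant, which the
synthetic stand-ins only partially emulate relative to real radiomic
panels.

## Problem sizes used in tests and the acceptance script

The full protocol defaults (1000 selection rounds, 500 x 3 evaluation, the
2592-point grid) remain the function defaults. The test-suite and the
acceptance script run the same code at smaller, stated sizes chosen as the
package's own trade-off between statistical resolution and desk-scale run
time: signal recovery at 20 master seeds x 100 rounds (tests) or 6 seeds
x 60 rounds (script); the negative control at 120 selection rounds and a
16-point grid; the protocol-count check at the full 500 x 3 with a
singleton grid. Each reported number states the size it was computed at.

## Known limitations

* The phantom texture model is stationary within the gland; real prostates
  have zonal anatomy, lesions and motion artifacts.
* Shape features vary little across phantoms (fixed geometry), so shape
  columns are nearly constant in phantom-derived tables; they are retained
  for structural fidelity and dropped automatically where zero variance
  would break z-scoring.
* Filter-derived (LoG/wavelet) features are not invariant to intensities
  just outside the ROI: finite kernels mix a neighbourhood, as in the
  reference extraction platforms. Exterior invariance holds exactly for
  the original-image classes.
* The SFFS gain threshold is evaluated on a single 3-fold split per round;
  its AUC estimates carry sd ~0.05, which both the selection frequencies
  and the null behaviour of the procedure inherit. This mirrors the
  published protocol rather than an estimator-optimal choice.
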