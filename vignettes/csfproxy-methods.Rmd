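---
title: "MRI-derived CSF proxy-markers: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-derived CSF proxy-markers: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cerebrospinal-fluid (CSF) concentrations of amyloid-beta 1-42 (abeta),
phosphorylated tau 181 (ptau) and total tau are core biomarkers of
Alzheimer's disease, but sampling them needs a lumbar puncture. Structural
MRI is noninvasive and widely available, and gray-matter atrophy carries a
signature of the same pathology. `csfproxy` implements a pipeline that

1. regresses the three CSF concentrations from 3D gray-matter density
   volumes with compact 3D convolutional networks (one single-output network
   per marker, SO; or one multi-output network with three heads, MO);
2. transfers the penultimate-layer activations of those regressors — the
   *proxy-markers* — to two binary classification contexts: diagnosis
   (CN vs AD) and progression prediction within MCI (sMCI vs pMCI);
3. compares against CSF-only baselines (published cutoffs and an
   intentionally overfit exhaustive threshold sweep); and
4. explains the regressors with integrated-gradients attribution maps,
   group-difference maps, and per-ROI summaries.

Because clinical imaging data cannot be redistributed, the package ships a
synthetic cohort generator that reproduces the statistical structure the
analysis relies on, so every stage is exercisable and testable end to end.

## The regression model

The backbone is a stack of convolution blocks — 3x3x3 convolution (no bias;
the following normalization makes it redundant), batch normalization, ReLU,
and 2x max-pooling — followed by global average pooling. The reference
channel progression is `64-128-192-192-128` (five blocks); the width and
depth are configurable and the desk-scale default used in tests is `8-16-32`
on a 32^3 grid, which trains in about two minutes per marker on one CPU.
Each regression head is two fully connected layers: a hidden layer of 64
units (whose ReLU activations are the latent embedding) and a linear scalar
output. An SO model has one head; the MO model attaches three heads to the
shared backbone, so its embedding is the 192-dimensional concatenation.

No deep-learning framework is available in the supported toolchain, so the
forward pass, backpropagation (including gradients with respect to the input
volume, needed for attribution) and the Adam optimizer are implemented in
the package itself; convolution runs as im2col plus BLAS matrix products
with compiled gather/scatter kernels. Correctness is pinned by
finite-difference gradient tests and by the integrated-gradients
completeness axiom.

## Loss strategies

Per-head training loss is the batch MSE. The MO model combines the three
head losses in one of two ways:

* **AL (average loss)** — the plain mean of the three MSEs.
* **WNL (weighted normalized loss)** — each marker keeps a running maximum
  of its batch loss; the current loss is divided by that maximum and the
  normalized losses are combined with fixed weights: abeta 50%, tau 25%,
  ptau 25%. On the first batch every positive loss is its own maximum, so
  the combined loss is exactly 1; thereafter the loss always lies in [0, 1].
  The running maxima are global over the run by default
  (`wnl_reset_per_epoch = TRUE` gives per-epoch maxima; the original
  description does not say which is meant, and global maxima make the
  normalization scale stable late in training). The gradient treats the
  running maximum as a constant, which is exact everywhere except at the
  isolated instants the maximum is raised.

### Target standardization

`train_regressor` z-scores the targets with training-fold statistics before
computing the loss, and de-standardizes predictions afterwards, so reported
MAE/MSE remain on the raw pg/mL scale and R2/EV are unaffected. This
deviates from treating raw pg/mL as the default loss scale: with Adam at
learning rate 0.001 and desk-scale epoch budgets, a head output cannot
traverse the ~1000 pg/mL target magnitude (Adam's per-step movement is
bounded near the learning rate), so raw-scale training cannot converge in
any CPU-feasible schedule. Setting `standardize_targets = FALSE` restores
the literal raw-scale loss.

## Training protocol

Adam (optionally SGD), learning rate 0.001, MSE/AL/WNL loss. The validation
coefficient of determination (R2) drives a reduce-on-plateau scheduler
(factor 0.5 after 7 epochs without improvement beyond 1e-4) and early
stopping (20 epochs without improvement); the parameters of the best
validation-R2 epoch are returned. The identical state machine is exposed as
`simulate_plateau_schedule()` so the decay/stop epochs can be audited
against scripted metric sequences. Splits come from
`monte_carlo_splits()`: repeated random subsampling (default 10
repetitions) into train/validation/test partitions, stratified by
diagnostic group and split at the subject level so no subject's sessions
straddle partitions. The train/val/test fractions (0.70/0.10/0.20) and the
batch size (8) are package choices — conventional values, not reproductions
of any published setting.

## Transfer to classification

Embeddings are standardized per dimension with training-fold statistics and
fed to an L2-regularized logistic regression (glmnet ridge; penalty
equivalent to unit inverse regularization strength at the training size —
a stable choice at 64–192 dimensions with small n). The decision threshold
is a 0.5 posterior; sensitivity/specificity are reported at that single
operating point, not optimized. Classification uses the same per-repetition
folds as the regression stage. A context-specificity check regresses age on
the same embeddings: latents optimized for CSF pathology should predict age
much worse than they predict the CSF markers (on synthetic cohorts age is
only weakly coupled to severity, so the check has a known expected outcome).

## Baselines

* Mean-prediction and constant-cutoff regression baselines; on its own
  fitting data the mean model has R2 = EV = 0 exactly.
* Published cutoff classifiers: abeta 977 pg/mL (below-cutoff positive),
  ptau 24.425 pg/mL and tau 263.79 pg/mL derived from the abeta cutoff by
  the ptau/abeta = 0.025 and tau/abeta = 0.27 ratios (above-cutoff
  positive). Values exactly at a cutoff count positive, matching the
  "<= cutoff abnormal" convention for abeta.
* An exhaustive threshold sweep whose candidates are midpoints of sorted
  distinct values plus infinite sentinels — a superset of every achievable
  dichotomy, so its best accuracy is the true maximum. It is evaluated on
  the data it optimizes, deliberately overfit, and flagged as such.

## Attribution

Integrated gradients with a zero-volume baseline and a midpoint Riemann rule
(default 64 steps; midpoint because it halves the error of the left-point
rule at no cost, and the linear-model closed form `w * x` holds at any step
count). Completeness — attributions summing to `f(x) - f(0)` — is enforced
in tests at 0.5% relative error with 256 steps. Subject maps are
post-processed with a 3D Gaussian (sd 2 voxels, truncated at 1.75 sd, i.e.
a 9x9x9 kernel) and min-max scaled to [0, 1] per subject. Scaling to [0, 1]
destroys sign information, yet the signs are scientifically meaningful
(abeta falls with atrophy, tau/ptau rise), so both products are kept: raw
signed maps feed sign analyses (`dominant_sign()`), scaled maps feed
group-level averaging. Group analysis produces the four group means and all
six pairwise difference maps; `rank_pair_magnitudes()` orders the pairs by
mean absolute difference inside signal ROIs (ties break alphabetically).

## The synthetic cohort

A latent non-negative severity per subject drives everything: group means
0 / 0.5 / 1.8 / 2.5 for CN / sMCI / pMCI / AD with within-group sd 0.25
(severity draws are floored at zero). These levels were chosen so that the
pairwise gaps rank (CN,AD) > (sMCI,AD) > (CN,pMCI) > (sMCI,pMCI) >
(pMCI,AD) > (CN,sMCI) — the ordering a disease-severity continuum should
impose on attribution differences. CSF markers are linear in severity
(slopes -420 / +10 / +95 pg/mL per unit for abeta / ptau / tau; intercepts
1450 / 15 / 170) with Gaussian noise (sd 150 / 5.5 / 50), clamped to
clinical ranges (abeta [212.3, 1700], ptau [8, 94.9], tau [80, 818] pg/mL).
The noise sds were calibrated once so the *pooled* marker standard
deviations under the default severity mixture approximate clinical
reference statistics (abeta ~458 vs ~486, ptau ~11.7 vs ~13.8, tau ~110 vs
~126 pg/mL); per-group clinical summaries are not public, so this pooled
calibration is a stand-in, not a reproduction. Opposite abeta vs ptau/tau
slopes automatically induce the expected pairwise correlations (negative
abeta-tau, positive ptau-tau).

Volumes are a smooth template (background plus denser ellipsoidal ROIs,
Gaussian-smoothed) with a *proportional* intensity reduction of
`atrophy_slope * severity` (default 8% per severity unit) inside designated
signal ROIs, plus spatially smoothed voxel noise (sd 0.02), clipped at
zero. Non-signal ROIs are untouched by severity, which is what makes the
age-specificity check informative. Corruption for QC testing zeroes the
bottom 20 axial slices. Ages follow `72 + 1.5 * severity + N(0, 5)`;
clinical visit dates sit at a N(0, 40)-day offset from imaging dates so
most, but not all, pairs fall inside the +/-90-day matching window.

What the generator does **not** emulate: anatomy (ROIs are ellipsoids, not
structures), registration error, scanner/site effects, longitudinal
correlation, and any nonlinearity in the severity-biomarker relation. A
green test therefore establishes that the pipeline recovers the signal it
is pointed at under its stated statistical structure — not clinical-grade
performance.

## Quality control and matching

QC correlates each volume with the voxelwise group-mean template: whole
volume, top 20 and bottom 20 axial slices (axial = third grid axis by
convention; on grids shallower than 40 slices the slab is capped at half
the depth). The pass thresholds are r >= 0.7 on all three checks — a
package choice, deliberately conservative: clean synthetic volumes
correlate with the template near 1, while a zeroed slab has undefined
correlation and is flagged failed outright. Visit matching takes the
nearest clinical visit within +/-90 days, breaking exact ties toward the
earlier visit (deterministic and auditable). Volumetric smoothing converts
an isotropic FWHM in mm to per-axis sigmas in voxels
(`sigma = fwhm / (voxel * 2 sqrt(2 ln 2))`, so 6 mm at 1.5 mm voxels gives
sigma ~1.699) and filters separably with reflect boundaries, which
preserves the mean of interior-supported volumes.

## Numerical and degenerate-input conventions

* Batch-norm epsilon 1e-5, momentum 0.1; evaluation mode uses running
  statistics, making inference deterministic and the attribution path
  piecewise-linear.
* WNL normalization at zero: 0/0 is defined as 0 (continuous limit).
* Constant target vectors make R2/EV undefined (`NA`), never an error for
  MAE/MSE; constant scores give AUC 0.5 by the tie convention; constant
  attribution maps min-max scale to all zeros.
* All randomness flows through named integer seeds; helper streams are
  derived deterministically and kept below 2^31.

## Known limitations

* The reference-width network on the full 121x145x121 clinical grid is
  supported by the code paths but not practical on one CPU; tests and the
  acceptance script run reduced widths on 32^3 grids.
* The NIfTI-1 reader/writer covers 3D scalar volumes (uint8/int16/int32/
  float32/float64, both endiannesses, gzip, slope/intercept scaling) and
  ignores orientation metadata beyond voxel size.
* The logistic transfer model is ridge-only; the elastic-net and
  kernel-ridge whole-brain comparisons are out of scope.
* Attribution significance testing is not provided (none is defined for
  the method); the regional summaries are descriptive.
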