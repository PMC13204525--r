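---
title: "Methods: habitat radiomics, compact volumetric models, and fusion for breast-PET response prediction"
author: "dpetfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat radiomics, compact volumetric models, and fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with HER2-positive breast cancer frequently receive neoadjuvant
chemotherapy, and whether a patient will reach pathologic complete response
(pCR) is clinically decisive but only known after surgery. Dedicated breast
PET produces high-resolution volumetric maps of FDG uptake whose spatial
organization — a metabolically active core against necrotic or stromal
low-uptake tissue, textural granularity, focal hot spots — plausibly carries
response-relevant signal before treatment starts. `dpetfusion` implements an
end-to-end modelling pipeline over such volumes: metabolic habitat
clustering, a large handcrafted radiomic feature bank with a selection
cascade and classical classifiers, compact CPU-trainable volumetric neural
networks, a single-slice intratumoral heterogeneity (ITH) score, and two
ways of fusing the handcrafted and learned representations, together with a
complete evaluation and interpretability suite.

Because no public cohort of dedicated breast PET with pCR outcomes exists,
the package ships a synthetic cohort generator whose statistical structure
matches what the analysis assumes. Every stage of the pipeline is exercised
and tested against these synthetic volumes.

## Cohort conventions

A primary cohort (default 129 cases) is split 70/30 into a training set and
a first test set by stratified random sampling (largest-remainder
allocation, so 129 cases give exactly 90/39); a second, smaller and
deliberately imbalanced block (default 18 cases at 77.8% prevalence) is
generated independently and kept aside, emulating a temporally separated
validation cohort. Default primary prevalence is 0.655. All fitting,
selection, and tuning happens on the training partition only; the no-leakage
property is asserted by tests that corrupt test labels and verify that every
fitted parameter is unchanged.

## The synthetic generator

Each case is an ellipsoidal tumor (semi-axes drawn from a configurable
range) on a quiet background:

* **Core–rim gradient.** In-mask intensity follows
  `rim + (core - rim) * (1 - r^2)` in normalized ellipsoid coordinates, with
  the core/rim uptake ratio set per class (`rim_core_contrast_by_label`).
* **Correlated texture.** Gaussian-filtered white noise with a per-class
  correlation length (`texture_granularity_by_label`, mm) multiplies the
  profile. This is the channel handcrafted texture features can detect.
* **Focal hot spots.** A per-class number of Gaussian bumps
  (`fragmentation_by_label`) at random in-core positions. Counting and
  localizing such foci is a spatial-pattern task suited to the image
  models, giving a second, partially independent signal channel so that
  fusion complementarity is testable.
* **Intensity scale.** Each volume is rescaled so its masked maximum
  (recorded as SUVmax) is drawn around 32 within 14–65, the SUV regime of
  the baseline clinical covariate.
* **Clinical covariates.** Age, Ki-67, cT, cN, grade, regimen and SUVmax
  are drawn with weak label-dependent shifts (default |log-odds| ≤ 0.4) so
  the clinical baseline stays mediocre by construction.

Defaults use a 32-voxel cubic grid at 1 mm isotropic spacing with tumor
semi-axes of 4–7 mm. These tumors are deliberately smaller than typical
clinical T2 lesions: the geometry is scaled down so that the full pipeline —
thousands of feature extractions and repeated network trainings — runs
on a single CPU at interactive timescales, while every statistical property
the tests rely on (texture scale contrast, habitat structure, focal counts)
is preserved at this scale. The device's true reconstruction spacing is not
asserted; spacing is configurable.

**What the generator does not emulate:** PET physics (attenuation, scatter,
partial-volume effects), irregular tumor shapes, multifocal disease, or any
attempt to match a real cohort's covariate distributions. Passing tests on
these cohorts demonstrates that the pipeline recovers planted signal of the
assumed kind — not that it would reach any particular performance on real
patients.

## Habitat segmentation

Within the smoothed ROI (Gaussian filter, default sigma 1 mm, normalized
kernel with half-sample symmetric boundaries — this makes the operator
doubly stochastic, so the grid mean is preserved exactly), voxels are
clustered on intensity alone into k = 2 habitats. One-dimensional 2-means
reduces to an optimal threshold, which the package finds exactly by scanning
all cuts of the sorted intensities (prefix-sum arithmetic). This removes
initialization sensitivity entirely; the partition is deterministic and
permutation-invariant, and tests compare it against a brute-force cut
enumeration and multi-start Lloyd iteration. The higher-centroid cluster is
the high-uptake habitat. A mean silhouette over the in-mask assignment is
reported as a quality diagnostic; k stays fixed at 2 (the silhouette never
overrides it). ROIs with intensity spread below tolerance, or with a cluster
smaller than `min_size` (default 8 voxels), are flagged degenerate and
treated as all high-uptake, because downstream extraction needs non-trivial
regions.

## The radiomic feature bank

Per region the bank is pinned to exactly 1688 features: 14 3D shape
descriptors from the original image, plus 93 intensity/texture features (18
first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) computed on the
original image and 17 derived images — 8 single-level wavelet sub-bands, 5
Laplacian-of-Gaussian scales (sigma 1–5 mm), and square, square-root,
logarithm, and exponential intensity transforms. Three regions (whole ROI,
high- and low-uptake habitat) give 5064 columns per case.

Numerical choices worth knowing:

* **Discretization** uses a fixed bin count (default 32) inside each
  region, which makes all texture features invariant to adding a constant
  to the image (tested).
* **Aggregation** of GLCM/GLRLM over the 13 unique 3D directions is by
  matrix merging (sum, then normalize) rather than per-direction feature
  averaging — one conventional IBSI aggregation choice, selected for
  speed and simplicity.
* **Wavelet sub-bands** are undecimated (stationary) single-level
  averaging/detail filter pairs, so sub-band images stay aligned with the
  ROI mask and no mask resampling is needed.
* **Shape**: mesh volume is approximated by the voxel volume and surface
  area by exposed voxel faces; maximum diameters use boundary voxels
  (deterministically thinned above 1000 points). These are voxel-level
  approximations, adequate for ranking and selection on synthetic data.
* **Degenerate habitats** produce missing region features that are imputed
  with column medians, with the affected case/region pairs recorded.

## Selection cascade and classifiers

Features pass a two-sided Mann–Whitney U filter (normal approximation with
tie correction, default alpha 0.05; retained columns are z-scored with
training statistics), then greedy mRMR (relevance minus mean redundancy,
mutual information on equal-frequency 8-bin discretizations, deterministic
tie-breaks, default m = 30; the quotient criterion is available behind a
flag), then an L1-penalized logistic regression over a log-spaced lambda
grid with lambda chosen by stratified 5-fold cross-validated binomial
deviance; the final set is the nonzero-coefficient features. On synthetic
cohorts the cascade keeps whatever survives — the selected count is a
data property, not a contract. Five classifiers (logistic regression with
an elastic-net grid, random forest, gradient-boosted trees, k-nearest
neighbors, Gaussian naive Bayes) are tuned by stratified 5-fold
cross-validated AUC and refit on the full training set; out-of-fold
probabilities of the winning configuration are retained for stacking.
A bootstrap stability analysis reruns the entire cascade on resampled
training rows and reports per-feature reselection frequencies.

## Compact volumetric models

Tumors are cropped with a 5-voxel margin (microenvironment context),
resampled trilinearly to 64×64×64 and z-scored per crop. Both architectures
then ingest this tensor through a fixed 4× average-pooling stem onto a
16-cube working grid with **two channels: pooled intensities and pooled
squared intensities**. The second channel keeps sub-pool second moments
linearly accessible — without it, average pooling erases exactly the
voxel-level dispersion statistics that distinguish focal from diffuse
uptake, and both models plateau near chance on the focal-geometry channel.

* `resnet3d_small`: a stem convolution followed by eight residual blocks in
  four stages (spatial sizes 8, 4, 4, 2; base width 8, doubled after the
  first stage), global average pooling, and two fully connected layers.
* `vit3d`: non-overlapping patches (default 16 at the 64-cube scale, so 64
  tokens), a linear projection to a 64-dimensional latent space with
  learned position terms, 3 pre-norm transformer layers (2 heads, GELU MLP
  of width 128, sigmoid-approximated GELU for speed), a final layer norm,
  token averaging and a linear head.

Training is minibatch Adam on binary cross-entropy, fully seeded (He-scaled
initialization, zero-initialized output head so an untrained model predicts
0.5). Convolutions and pooling are C++ (im2col + BLAS); backpropagation is
derived by hand and verified against numerical differentiation in the test
suite. Architecture and hyperparameter selection use stratified 5-fold
cross-validation within the training set only, scored by mean across-fold
AUC; the winner is retrained on all training rows. Pretrained video or
medical-imaging weights are out of scope; the models are compact enough to
train on one CPU in seconds to minutes.

## ITH score

On the axial slice with the largest in-mask area (ties to the lowest
index), every in-mask pixel receives a 104-dimensional descriptor of its
3×3 in-mask neighborhood: 19 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14
GLDM, 5 NGTDM (4-direction / 8-connectivity 2D variants, fixed-bin-count
window discretization, default 8 bins), plus 10 2D shape descriptors of the
window's in-mask geometry. Pixels are clustered by k-means on z-scored
descriptors, with k chosen from 2–5 by mean silhouette (fixed-k override
available). The heterogeneity score is pinned as

\[ \mathrm{ITH} = 1 - \sum_i p_i \cdot f_i , \]

where \(p_i\) is cluster *i*'s area fraction and \(f_i\) the fraction of its
area held by its largest 4-connected component. The published score this
operationalizes combines cluster area, connectivity, and spatial
distribution but its exact formula is not reproduced here; this pinned form
uses exactly those ingredients, is 0 precisely when every cluster is one
connected component, grows monotonically under fragmentation (tested), and
is invariant to cluster relabeling and intensity rescaling. Biological
comparability with the CT/MRI-era score is not claimed. A univariate
logistic model on the score, with AUC and a two-sided Mann–Whitney p-value,
completes the branch; the score deliberately stays out of the fusion
models.

The per-pixel extractor has two engines: a single-pass C++ implementation
(default; hundreds of windows per case) and an R reference path through the
same feature functions used by the 3D bank. The test suite asserts their
equality, so the fast path is always anchored to the readable one.

## Fusion

**Decision-level (stacking).** The meta-learner is a logistic model on the
logit-transformed branch probabilities (clipped to [1e-6, 1-1e-6]). Training
inputs are out-of-fold probabilities — the refit-probability variant exists
behind a flag but is not the default, because in-sample meta-inputs are
optimistically biased. A small ridge-strength / class-weighting grid is
tuned by stratified 5-fold CV AUC on training rows; the frozen coefficients
are then applied unchanged to test probabilities.

**Feature-level.** The selected radiomic features (z-scored with training
statistics) pass through a learnable linear projection to the pooled-
representation width and are added element-wise to the pooled network
representation; the whole network is retrained end-to-end under the same
procedure. The projection is zero-initialized, so training starts exactly
at the image-only solution (asserted to machine precision), and zeroing the
radiomic inputs at inference reproduces the image-only pathway. The
projection carries no bias, keeping the residual-addition semantics clean.

## Evaluation suite

Headline metrics use a fixed probability cutoff of 0.5 (sensitivity,
specificity, accuracy, PPV, NPV, with undefined ratios flagged rather than
silently dropped); AUC is the pair-counting estimator with ties at one
half. Uncertainty is reported with class-stratified bootstrap percentile
intervals (default B = 2000). Precision–recall curves use step-interpolated
average precision. Decision-curve analysis reports net benefit against
treat-all/treat-none over a 0.01-step threshold grid and extracts maximal
beneficial intervals (strict dominance over both references), reporting the
longest as the final continuous range. The Hanley–McNeil closed form gives
the AUC variance, and power against AUC = 0.5 uses the null-variance
critical value by default (the alternative-variance variant is exposed,
since the published convention varies). A reconstruction utility inverts
printed two-decimal sensitivity/specificity pairs into integer confusion
matrices (rounding half away from zero), flagging ambiguity — useful for
checking that reported metric sets are internally consistent. The clinical
baseline is an elastic-net logistic model on z-scored continuous and
one-hot-encoded categorical covariates, tuned like every other branch.

## Interpretability

Grad-CAM for the convolutional branch weights channel activations at a
chosen residual block (default the last stage) by the global-average
gradient of the logit, rectifies, trilinearly upsamples to the input cube
and max-normalizes; all-zero maps are flagged degenerate instead of being
normalized. For linear models (the radiomics logistic model and the
stacking meta-learner), SHAP values are exact and closed-form on the
log-odds scale: `coef * (x - background_mean)` with additivity holding to
machine precision (tested). Pearson correlation matrices of selected
features flag zero-variance columns.

## Problem sizes used by the test suite

The simulation studies in the acceptance tests use 120 training with 300
held-out cases (three seeds) for the recovery and fusion-complementarity
studies, 100 training with 400 held-out cases for the null study, 500
replications with B = 500 resamples for bootstrap coverage, and 50,000
replicates for the Monte-Carlo check of the Hanley–McNeil variance. These
sizes were chosen so the whole suite runs on a single CPU in well under
half an hour while leaving the stochastic tolerances meaningful.

## Known limitations

* The generator is schematic; no claim of PET physical realism is made, and
  real-cohort performance figures are not reproducible from it.
* Shape descriptors are voxel-based approximations, not mesh-based.
* The ITH formula is this package's operationalization of a score whose
  published form is not reprinted; comparisons across implementations
  should be made with care.
* The compact networks are width-reduced, structurally faithful stand-ins
  trained from scratch; transfer-learning comparisons are out of scope.
* Multifocal or bilateral disease, DICOM handling, and scanner-specific
  SUV calibration are out of scope.
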