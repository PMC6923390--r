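---
title: "Radiomic grading of malignant gliomas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic grading of malignant gliomas: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliorad` implements an end-to-end radiomics pipeline for binary grading
of malignant gliomas (WHO grade III vs IV) from two co-registered
structural MRI channels (CE-T1 and T2) with a tumor mask that excludes
edema. This vignette explains the science implemented in the package,
the parameters that matter, the synthetic data model used to validate
it, and the design decisions made where the design was genuinely open.

## The pipeline and its assumptions

The method assumes channels are already co-registered per subject (no
registration is performed) and that a brain mask is available — the
phantom generator provides one; for real data a supplied mask or the
nonzero-intensity support can be used. The stages are:

1. **Spatial harmonization.** Images are resampled to 1-mm isotropic
   voxels with tensor-product cubic splines; binary masks use
   shape-based interpolation: the signed Euclidean distance map
   (positive inside) is computed exactly with a separable
   lower-envelope distance transform, interpolated with the same cubic
   splines, and thresholded at `>= 0` (a tie at exactly zero counts as
   inside, a deterministic boundary rule). Resampling precedes
   normalization so the intensity statistics refer to the analysis
   grid. Shape-based interpolation preserves topology for compact
   masks; the test suite verifies single-component preservation and
   volume preservation within 15% for digital spheres of radius 5+.
2. **Intensity normalization.** Whole-brain Z-scoring with the
   *population* SD over brain voxels (the common imaging convention;
   self-consistent in that the within-mask SD is exactly 1 afterwards).
   Voxels outside the brain get the same affine map. A constant image
   is an error, not a silent pass-through.
3. **Wavelet filtering.** A single-level, undecimated (stationary) 3D
   Coiflet filter bank produces the eight sub-bands HHH...LLL (label
   character 1/2/3 = filter along x/y/z). The undecimated form keeps
   every sub-band on the input grid, so one tumor mask serves all nine
   image versions; decimated output would break mask alignment.
   Coiflet order 1 is the default (order is configurable and recorded
   in feature provenance); boundary handling is symmetric
   (edge-repeating) extension, the standard choice for image filter
   banks. The high-pass filter is the quadrature mirror of the
   low-pass filter; the DC gain of the low-pass branch is `sqrt(2)`.
4. **Feature extraction.** The 5912-dimensional space decomposes as
   `8 + 2 x (9 x 38 + 9 x 5 x 58)`: 8 shape features computed once from
   the mask (forced by the total: computing shape per sequence would
   give 5920); per sequence and image version, 18 intensity and 20
   histogram features; per version and quantization depth (4-8 bit),
   11 GLCM + 13 GLRLM + 13 GLSZM + 16 NGLDM + 5 NGTDM texture features.
   Quantization clips ROI values to the ROI mean ± 3 population SD and
   bins them uniformly into `2^bits` levels (right-closed top bin;
   a zero-variance ROI maps to level 1). Histogram features reuse the
   same quantizer at a fixed 6 bit so one discretization rule serves
   both. Sub-band ROI statistics are recomputed per filtered image,
   since sub-band value ranges differ from the original.
5. **Feature selection.** A two-tailed Wilcoxon–Mann–Whitney screen at
   strict `P < 0.001` (exact p-values by the null rank distribution for
   tie-free groups with `min(n) <= 8`, otherwise the normal
   approximation with tie and continuity correction; no
   multiple-testing correction, by design), followed by L1-penalized
   logistic regression with unpenalized intercept, fitted by cyclic
   coordinate descent. The penalty weight is tuned over a log grid on
   `[1e-6, 1e2]` (33 points by default) by repeated stratified CV
   (5-fold x 5 by default) maximizing mean held-out AUC, ties broken
   toward the larger penalty (sparser model). Screened features are
   standardized with training-fold statistics only; held-out rows are
   transformed with those statistics.
6. **Classification and evaluation.** Five model families: ridge
   logistic regression, RBF-kernel SVM, a single-hidden-layer neural
   network, a random forest with 1000 trees, and Gaussian naive Bayes
   (untuned). Hyper-parameters are tuned by the same repeated
   stratified CV protocol. LOOCV reruns the *entire* selection stage
   inside every fold — screening, penalty tuning and the final LASSO
   fit never see the held-out subject — and pools the out-of-fold
   scores into one ROC/AUC per model; hard labels use a 0.5 threshold
   on the probability scale. Independent validation restricts to the
   descriptors selected in *all* LOOCV folds, refits on the full
   primary cohort, and scores the validation cohort once. Grade IV is
   the positive class everywhere.

## Texture-matrix conventions

The matrix definitions follow the 3D IBSI-style conventions: GLCM and
GLRLM merge the 13 unique direction vectors at Chebyshev distance 1
into a single matrix (the "merged" aggregation; per-direction variants
are out of scope); the GLCM is symmetrized and normalized to unit mass.
GLSZM zones are 26-connected components of equal level; NGLDM uses the
26-neighborhood with coarseness tolerance `alpha = 0`; NGTDM excludes
voxels with no in-ROI neighbor and its coarseness uses
`1 / (1e-12 + sum(p_i s_i))` so uniform ROIs stay finite. All entropies
are in bits. Degenerate ROIs (a single voxel, a single level) produce
zero-valued features for the affected family with a warning rather than
an error, so cohort extraction never aborts. Every builder is verified
against an exhaustive brute-force enumeration on hundreds of random
small ROIs, exactly, and the formulas against hand-worked cases.

The exact membership of the 18/20/11/13/13/16/5 per-family lists is a
registry choice documented in `FEATURE_REGISTRY`; the sets are
IBSI-named, sized to the design counts, and include the named features
the selection stage is known to favor (intensity median and root mean
square; GLRLM run-length variance; GLSZM gray-level non-uniformity
normalized and gray-level variance; NGLDM high dependence low
gray-level emphasis).

## The phantom: what it emulates and what it does not

`generateCohort()` produces, per subject, an ellipsoidal brain with a
smooth random background field (unit SD), a tumor grown from a radial
seed bump plus a bumpy Gaussian random field thresholded inside the
brain (kept 26-connected), class-dependent tumor properties, and
additive Gaussian voxel noise on both channels. Defaults define the
documented planted-effect conditions:

| parameter | default | meaning |
|---|---|---|
| `intensityShift` | 1.5 | grade-IV CE-T1 tumor brightening, Z-units |
| `textureSmoothnessRatio` | 2 | grade-III texture correlation length / grade-IV (IV rougher) |
| `tumorRadiusRatio` | 1.25 | grade-IV / grade-III tumor radius |
| `noiseSigma` | 0.3 | additive Gaussian noise SD, Z-units |
| `nPerClass` | 18 / 36 | III : IV imbalance of 1 : 2, the typical malignant-glioma ratio |
| `gridShape` | 64³ | voxels (1 mm isotropic) |

Noise is additive Gaussian on Z-scored intensities — the simplest model
preserving the pipeline's assumptions; a Rician option is out of scope.
Texture is planted as Gaussian-smoothed white noise with class-specific
kernel width, which the wavelet/texture features detect with just two
parameters. Per-subject RNG substreams are derived from
`(seed, subject index)`, so identical configurations reproduce
bit-identical volumes and growing a cohort never perturbs existing
subjects. The phantom does **not** simulate MRI physics (no TR/TE
contrast mechanisms, bias fields, or coil profiles), scanner or
delineation variability, or an edema compartment — passing tests
demonstrate the pipeline's statistical and numerical correctness on
data with its assumed structure, not clinical performance.

## Numerical choices

* **Coordinate descent.** The penalized logistic objective is minimized
  by iteratively reweighted least squares with cyclic soft-thresholding
  coordinate descent on each weighted quadratic (weights floored at
  1e-5), active-set iteration, warm starts along the penalty path
  (largest penalty first), and a step-halving safeguard that makes the
  true penalized objective provably non-increasing across outer
  iterations. At `lambda >= max_j |sum_i x_ij (y_i - mean(y))|` the
  slope vector is exactly zero — the test suite asserts this
  subgradient bound, agreement with an unpenalized `glm` fit at
  vanishing penalty, and a brute-force objective-grid oracle.
  Convergence is declared when the largest coefficient change per outer
  iteration falls below `tol` (1e-7 for final fits); path fits inside
  CV use a looser 1e-5 and a 30-iteration cap, since held-out AUC is
  insensitive to the tail of the trajectory on separable resamples
  where the unpenalized optimum diverges.
* **AUC.** Rank-based (Mann–Whitney) with ties counting 1/2,
  equivalent to the trapezoidal area under the empirical ROC.
* **Stratified folds.** Within-class round-robin after a seeded
  shuffle; a class smaller than the fold count is an error rather than
  a silent degenerate split.
* **SVM scores.** Decision values are mapped through a logistic
  calibration fitted on training data only (the operating point and
  probability scale are otherwise undefined for margin classifiers);
  naive-Bayes within-class SDs are floored at 1e-6 so constant
  features cannot produce NaNs.
* **Degenerate screens.** A training split in which no feature passes
  the screen raises a typed condition; LOOCV records the fold as failed
  and continues, reporting the count.

## Desk-scale study conditions

The package's own validation experiments (the end-to-end blocks of the
test suite) use these problem sizes, chosen so the full suite runs on one
CPU: planted-effect arm — five cohorts (seeds 1-5) of 30 + 30 subjects
on 32³ grids (1-mm voxels) with the default effects; neutral arm —
three cohorts of 30 + 30 on 32³ grids with all class effects switched
off; selection recovery — five synthetic 60 x 5912 feature tables with
5 informative columns (2 Z-unit shift). The planted effects are defined
in Z-units and dimensionless ratios, so their detectability does not
depend on the grid scale (tumors still span hundreds to thousands of
voxels at 32³). Inside these experiments the penalty grid has
10 points, penalty tuning uses 3-fold x 1-repeat CV, model tuning
3-fold x 1 with reduced grids (the SNN grid is hidden units {3, 8} x
decay; hidden layers wider than the training sample size are degenerate
at n of a few dozen, which is why the desk-scale grid stays small). The
full-protocol defaults (33-point grid, 5 x 5 CV, wider model grids)
remain the function defaults and are what a study-scale run would use.

## A note on pooled LOOCV AUC under the null

Pooling out-of-fold scores into a single ROC — the protocol implemented
here — is known to be optimistically biased when feature selection is
driven by cohort-level chance patterns: radiomic features are massively
redundant, so a spurious between-class difference in one underlying
image statistic propagates to a stable cluster of features that passes
the screen in (nearly) every LOOCV fold, and the pooled AUC then tracks
that cluster's within-cohort separation rather than 0.5. At n = 60 the
most separating of several thousand (effectively a few hundred
independent) chance features has a cohort AUC around 0.75-0.85, and
neutral-phantom pipelines can post pooled LOOCV AUCs well above chance
even though no generative class difference exists; per-fold selection
prevents leakage into any individual score but not this ranking-level
optimism. Two opposing mechanisms push the other way: per-fold models
with near-zero slopes score held-out subjects essentially at the
training prevalence, which differs systematically by the held-out
subject's class (29/59 vs 30/59) and anti-ranks them — in the limit of
constant-score models the pooled AUC is exactly 0 — and winner's-curse
regression of the max-selected statistic adds a pessimistic component.
A neutral-phantom run therefore lands far above or far below 0.5 about
as often as near it. All three effects shrink with n (chance extremes
scale like `1/sqrt(n)`) and are negligible next to a real effect of 1+
Z-units; at study-scale n in the hundreds the pooled LOOCV ROC is the
pragmatic instrument the field treats it as. The neutral-arm check in the test suite runs at
fixed seeds and reports whatever they produce; these phenomena are the
expected explanation when its median falls outside the nominal chance
band.

## Known limitations

* No inter-modality registration, bias-field correction, or scanner
  harmonization (e.g. ComBat); inputs are assumed co-registered and
  comparable after Z-scoring.
* No 2D slice-wise features, per-direction texture variants, or
  co-occurrence distances beyond 1.
* The histogram/intensity/texture registries are fixed-size documented
  choices; swapping individual members changes feature identities but
  not the pipeline mechanics.
* DeLong confidence intervals for AUC and class-imbalance resampling
  are out of scope; across-model summaries use the sample SD with a
  t-based 95% CI.
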