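---
title: "Radiomics-based outcome prediction for Gamma Knife radiosurgery: methods and design"
author: "GKRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics-based outcome prediction for Gamma Knife radiosurgery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GKRadiomics)
```

# The problem

Brain metastases (BMs) of non-small cell lung cancer treated with Gamma
Knife radiosurgery (GKRS) show heterogeneous responses: some lesions remain
controlled, others progress, and patient survival varies widely. Two binary
prediction tasks are studied here on multi-contrast pre-treatment MRI (T1w,
T1c, T2w) plus routine clinical covariates:

* **local tumor control** — lesion-wise; a lesion whose volume grows by
  more than 10% between the pre-treatment scan and the last follow-up is
  labeled *poor* (progression), anything else *good*;
* **overall survival (OS)** — patient-wise; patients at or above the cohort
  median OS are *good*, below it *poor*.

Three model families are compared on identical machinery: clinical
covariates only, radiomic features only, and their combination.

Because no patient images are distributed, the package is exercised
entirely on synthetic phantom cohorts whose statistical structure is
planted and therefore known exactly. Every stage of the pipeline — image
preprocessing, feature extraction, labeling, selection, balancing, training
and comparison — is the same code a real cohort would pass through.

# The synthetic phantom generator

`makePhantomCohort()` draws, per patient, a balanced latent outcome class
(`good`/`poor`) and builds three aligned isotropic volumes (T1w/T1c/T2w)
containing 1–3 ellipsoidal lesions:

* **Geometry.** Per-axis semi-axes are the mean radius jittered ±30%, so
  lesions are anisotropic ellipsoids; masks of one patient never overlap.
  Placement failures after 100 draws raise an error naming the patient.
* **Texture planting.** Inside each lesion an additive Gaussian noise field
  smoothed to a correlation length of about 2 voxels is scaled by a
  class-dependent amplitude (defaults 0.15 for *good*, 0.45 for *poor*,
  relative to the lesion–background intensity difference of the contrast).
  The *poor* class is thus texturally more heterogeneous — detectable by
  co-occurrence and histogram features but invisible to the clinical
  covariates.
* **Outcome plumbing.** Follow-up volumes are drawn from class-conditional
  relative-change ranges ([−50%, +5%] for *good*, [+15%, +90%] for *poor*)
  that avoid the +10% decision boundary, so the volume rule recovers the
  latent class exactly; with probability `flipRate` a lesion draws from the
  other class's range, injecting label noise. OS is log-normal per class
  (default medians 24 vs 8 months, sdlog 0.5) *truncated at the geometric
  midpoint* of the two medians. With balanced classes this makes the
  cohort-median split recover the latent classes exactly at flip rate 0 —
  label noise is injected through the flip rate rather than through
  distributional overlap, which keeps the labeling stage exactly testable.
* **Clinical covariates.** KPS ≥ 90, extracranial metastases,
  primary-tumor control and lesion count differ between classes by
  configurable standardized effect sizes (defaults 0.8/0.8/0.5/0.5,
  oriented so that good-prognosis values are more frequent in the *good*
  class). These defaults give the clinical-only model real but imperfect
  discrimination, so the three-way model comparison is non-trivial.

Defaults (32³ voxels at 1 mm, 20 patients, radii 3–6 mm) were chosen once
as a realistic desk-scale emulation of a GKRS cohort: BMs of 5–20 mm
diameter on 1 mm isotropic MRI. The texture amplitudes are free parameters
of the generator — no published cohort constrains intra-class variance
magnitudes — and are documented in the configuration rather than calibrated
to any dataset.

What the phantoms deliberately do **not** model: brain anatomy, bias
fields, acquisition physics, partial-volume effects, scanner differences.
Passing tests therefore demonstrate that the pipeline recovers planted
effects through the full image-to-model path, not that it would achieve any
particular performance on clinical data.

# Preprocessing

The preprocessing chain is resample → register → normalize:

1. **`resampleIsotropic()`** brings every volume to 1 mm isotropic spacing;
   images are interpolated trilinearly, masks with nearest-neighbour (mask
   fractions are never interpolated).
2. **`rigidRegister()`** aligns T1w/T2w to the T1c grid with a
   six-parameter rigid transform maximizing 32-bin joint-histogram mutual
   information, optimized by two-level multi-resolution Nelder–Mead
   (convergence tolerance 1e-4, parameters scaled so 0.05 rad ≈ 2 mm).
   The final metric value is returned for quality logging; values below
   0.1 nats (about the level of unrelated noise, whose joint-histogram bias
   is ≈ (B−1)²/2N nats) set `quality_ok = FALSE`. On the package's smooth
   phantoms, perturbations up to 5° and 5 mm are recovered with median
   error well under half a voxel.
3. **`zscoreNormalize()`** standardizes each volume by its whole-image mean
   and SD (background included); constant volumes map to zero with a
   warning.

Whether normalization should precede or follow resampling into the T1c
grid is not fixed by common practice; normalizing last means native and
registered images are standardized identically, which is the behavior
implemented here. Phantom cohorts are generated already aligned on a
common grid, so `runPipeline()` performs registration only when the config
sets `register = TRUE`; the registration operation itself is exercised
directly by its tests.

# The 1763-feature profile

Per lesion: for each contrast, the original volume and its eight
undecimated 3D Coiflet-1 subbands (LLL … HHH; letters are the low/high-pass
choice per image axis, in axis order) each contribute 16 histogram + 49
texture features → 9 × 65 = 585 per contrast; plus 8 mask geometry
features: 3 × 585 + 8 = 1763. Design choices:

* **Undecimated transform.** Subbands stay on the input grid, so the lesion
  mask applies unchanged — no mask downsampling convention is needed.
  Boundaries use half-sample symmetric extension.
* **Discretization.** Texture families and the binned histogram statistics
  use 32 equal-width levels over the in-mask min–max of each image set
  independently; the top bin is right-closed; constant ROIs collapse to
  level 1. Fixed-bin-number is the usual convention for Z-scored MRI.
* **The 49 texture features** split 26 GLCM + 13 GLRLM + 10 LBP:
  * *GLCM*: symmetric co-occurrence at displacement 1 along the 13 unique
    3D directions, features computed per direction and averaged. The 26
    names are the standard co-occurrence set (joint, difference and sum
    statistics, energy/contrast/dissimilarity, the four inverse-difference
    variants, correlation, autocorrelation, cluster tendency/shade/
    prominence, the two informational measures of correlation) plus
    Haralick's maximal correlation coefficient.
  * *GLRLM*: maximal same-level runs along the same 13 directions (mask
    gaps break runs); the 13 classical run-length features.
  * *LBP*: 8-neighbour radius-1 rotation-invariant uniform codes computed
    slice-by-slice, pooled over slices into the normalized 10-bin code
    histogram.
* **Degenerate conventions** keep every vector finite: IMC1, correlation
  and the maximal correlation coefficient are 0 when the relevant marginal
  entropy or variance vanishes; skewness/kurtosis are 0 for constant ROIs;
  directions without a valid voxel pair are skipped in the average, and an
  ROI with no pair in any direction takes the single-entry-matrix values.
* **Histogram family**: entropy and uniformity are computed on the 32-bin
  discretized distribution; energy is the raw sum of squared intensities
  (computing it on the binned distribution would duplicate uniformity).
* **Geometry** uses voxel counting for volume and exposed-face counting for
  surface area. Face counting is deterministic and exactly checkable
  against enumeration, but overestimates smooth surfaces by up to a factor
  1.5 (the average of |n_x|+|n_y|+|n_z| over a sphere); sphericity and
  compactness values are therefore comparable between lesions but are not
  mesh-quality estimates, and a digitized ball scores *below* a cube.

The direction set is closed under axis permutations and 90° rotations, so
the direction-averaged GLCM/GLRLM features are invariant to those
transformations (tested to 1e-6). Every family is validated against a
brute-force oracle — dense convolution for the wavelets, pair enumeration
for GLCM, line walking for GLRLM, bitstring enumeration for LBP, direct
formulas for the histogram, face counting plus all pairwise distances for
geometry — to 1e-9 on small fixtures.

# Labeling and table assembly

`labelTumorControl()` implements the +10% rule with the boundary (exactly
+10%) counting as *good*; `labelSurvival()` splits at the cohort median
with the boundary counting as *good*. Both boundary conventions are
documented choices; the underlying wording ("more than 10% increase",
median split) leaves them open. The survival median is computed on the
full analyzed cohort before splitting — it is a cohort descriptor, and
users should note this is leakage-relevant if the label were recomputed
per training set. Local control is modeled lesion-wise; survival
patient-wise using only the largest lesion's features
(`largestBMPerPatient()`, ties broken by smallest lesion id with a
message). Clinical covariates are binary flags, the lesion count, and the
log-transformed baseline volume.

# Modeling

The pipeline per view is: stratified 70/30 hold-out → Welch t-test ranking
→ NearMiss-2 balancing → sequential forward selection → Bayesian-optimized
RBF SVM → test-set evaluation → paired bootstrap comparison.

* **Split.** Stratified by class; lesion-wise tables are additionally
  grouped by patient so no patient straddles the split (stricter than an
  ungrouped split, which is the safe default when within-patient
  correlation exists). Grouping takes precedence over hitting the 70%
  fraction exactly.
* **Step-1 selection.** Welch's unequal-variance t-test per radiomic
  feature on the training set; keep p < 0.05, return the 25 smallest.
  Zero-variance features get p = 1. Welch is the safer reading of a
  generic "two-sample t-test".
* **Balancing.** NearMiss-2 keeps the majority samples with the smallest
  average Euclidean distance (standardized features) to their k = 3
  farthest minority samples, until counts equalize.
* **Step-2 selection.** Greedy forward selection maximizing the stratified
  5-fold CV AUC of the RBF SVM (cost 1, gamma 1/d during the wrapper);
  stop when no addition improves the criterion by more than 1e-4; the
  empty model scores 0.5. AUC is used as the wrapper criterion because it
  is the headline evaluation metric. Note that greedy CV maximization
  accrues selection optimism under the null: the expected best-candidate
  gain is ≈ 1.5·σ(AUC) per step, far above any fixed tolerance, so a few
  spurious selections at chance-level criterion are expected on pure
  noise; the null behavior is bounded by tests rather than assumed away.
* **Training.** `trainSVM()` standardizes with training statistics and
  searches log-uniform C ∈ [1e−3, 1e3], γ ∈ [1e−4, 10] by
  expected-improvement Bayesian optimization (Latin-hypercube initial
  design, Gaussian-process surrogate with squared-exponential kernel,
  lengthscale 0.25 on the unit square), maximizing the same stratified
  5-fold CV AUC; the final model refits on the full training set at the
  best point. Everything is deterministic under a fixed seed.
* **Evaluation.** AUC by the Mann–Whitney rank statistic over decision
  scores (ties count 1/2); accuracy, sensitivity and specificity at the
  natural score threshold 0, with *poor* as the positive class.
* **Comparison.** 100 bootstrap resamples of the test set, resample
  indices shared across models (paired); per metric and model pair a
  paired t-test, significant at α/number-of-pairs (Bonferroni). Resamples
  that lose a class are redrawn. Identical models yield zero differences
  and p = 1 by convention.

Clinical-only models skip the radiomic selection steps but share the
split, balancing, training and evaluation machinery, so the three views
differ only in their predictors. If step 1 finds no nominally significant
feature, or SFS selects none, the single best-ranked feature is used so a
radiomics model always exists (relevant only near the null).

# Reproducibility

`runPipeline()` fans a master seed out to every stochastic stage through a
fixed integer derivation, writes all artifacts (NIfTI cohort, feature
CSV, selected-feature reports, summary JSON) with MD5 content hashes, and
reproduces the hashes of deterministic stages on rerun. The problem sizes
used by the automated checks — e.g. 16³–20³ grids with 2.5–3.5 mm lesions,
24-patient cohorts over 10 seeds for planted-effect recovery, a
200-lesion null cohort, 100 registration trials — were chosen once as the
smallest scales at which the planted effects are unambiguous; the
generator's scientific defaults remain those stated above.

# Known limitations

* Phantoms have no anatomy; absolute metric values on phantoms say nothing
  about clinical performance, only about the pipeline's ability to recover
  known structure.
* Face-counted surface areas overestimate smooth shapes (above).
* The survival labeling uses an uncensored cohort median, as appropriate
  only when follow-up is complete.
* The exact 16-histogram/49-texture inventory is fixed by this package's
  registry; other standard-compliant inventories of the same counts exist.
* Registration assumes the multi-contrast volumes already share a spacing
  and roughly overlapping fields of view; it performs no initial global
  search.
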