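# GKRadiomics

MRI-radiomics prediction of Gamma Knife radiosurgery (GKRS) outcomes for
brain metastases (BMs), as a fully tested, reusable R pipeline exercised on
synthetic phantom cohorts.

## The problem

After single-session radiosurgery of a brain metastasis, two questions
matter clinically: will *this lesion* stay controlled (no more than a 10%
volume increase at last follow-up), and how long will *this patient*
survive (dichotomized at the cohort median)? Routine clinical covariates
(Karnofsky performance status, extracranial metastases, primary-tumor
control, lesion count and volume) predict both imperfectly. The hypothesis
the pipeline operationalizes is that quantitative texture of the
pre-treatment multi-contrast MRI — intra-tumor heterogeneity — carries
additional signal.

The pipeline implements, end to end:

1. **Phantom cohorts** (`makePhantomCohort()`): aligned T1w/T1c/T2w volumes
   with ellipsoidal lesions whose intra-lesion texture heterogeneity,
   clinical covariates and outcome labels carry *planted*, known effects —
   so every downstream stage is testable without patient data.
2. **Preprocessing** (`resampleIsotropic()`, `rigidRegister()`,
   `zscoreNormalize()`): 1 mm isotropic resampling, six-parameter rigid
   mutual-information co-registration to T1c, whole-image Z-score
   normalization.
3. **Radiomics** (`extractAllFeatures()`): 1763 features per lesion —
   per contrast, 16 histogram + 49 texture features (26 GLCM, 13 GLRLM,
   10 rotation-invariant uniform LBP codes) on the original image and on
   each of 8 undecimated 3D coif1 wavelet subbands (585 per contrast),
   plus 8 mask geometry features: 3 × 585 + 8 = 1763.
4. **Labeling** (`labelTumorControl()`, `labelSurvival()`,
   `largestBMPerPatient()`): the +10% volume rule lesion-wise; the
   median-OS split patient-wise on the largest lesion's features.
5. **Modeling** (`holdoutSplit()`, `ttestRank()`, `nearMiss2()`,
   `sfsSelect()`, `trainSVM()`): stratified (patient-grouped) 70/30
   hold-out; Welch t-test ranking to ≤ 25 candidates with p < 0.05;
   NearMiss-2 undersampling to equalize classes; greedy sequential forward
   selection under a 5-fold CV-AUC wrapper; RBF SVM with
   expected-improvement Bayesian hyperparameter optimization over
   log-uniform C ∈ [1e−3, 1e3], γ ∈ [1e−4, 10].
6. **Evaluation** (`evaluateModel()`, `bootstrapCompare()`): AUC (rank
   statistic), accuracy, sensitivity, specificity; 100 paired bootstrap
   resamples of the test set and Bonferroni-corrected paired t-tests
   between the clinical, radiomics and combined models.

`runPipeline()` chains all stages under one master seed and writes
self-describing run directories (cohort NIfTI files, feature CSV,
selected-feature reports, summary JSON with MD5 hashes). A thin CLI
wrapper lives in `inst/cli/gkrad.R`.

## Worked example

```r
library(GKRadiomics)

cfg <- defaultRunConfig(nPatients = 10L, gridShape = c(16L, 16L, 16L),
                        lesionRadius = c(2.5, 3.5),
                        lesionsPerPatient = c(1L, 2L),
                        searchIterations = 8L, bootstrapB = 30L, seed = 5L)
res <- runPipeline(cfg, outDir = "demo_run")
evalMetrics(res$reports$survival)
#>           auc accuracy sensitivity specificity
#> clinical    0      0.5           0           1
#> radiomics   1      1.0           1           1
#> combined    1      0.5           0           1
```

Each row is one model view evaluated on the held-out test patients of this
10-patient demo (a 3-patient test set — the extreme 0/1 values are small-n
artifacts; the package's automated checks use 10 seeds and larger cohorts).
With the default generator both texture and clinical effects are planted,
so the radiomics view separates the survival classes here while the
clinical view, on three test patients, does not. `demo_run/` then contains
the cohort (NIfTI + clinical CSV + JSON manifest), `features.csv`
(lesions × 1763), per-view selected-feature reports and `summary.json`.

At realistic scale (24 patients, 10 seeds, texture-only effects) the
radiomics view beats the clinical view on test AUC in ≥ 8/10 seeds, and
with both effects planted the combined view attains the highest mean AUC —
the directional pattern the three-model comparison is designed to detect.
See `tests/testthat/test-acceptance.R`.

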