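---
title: "Methods: VOI-based FDG-PET classification of prodromal Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOI-based FDG-PET classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Regional cerebral glucose metabolism, imaged with [18F]FDG-PET, is reduced
in a characteristic pattern years before Alzheimer-type dementia is
diagnosed: precuneus, posterior cingulate, temporo-parietal and (less
prominently) frontal cortices, often with left-right asymmetry in the
prodromal phase. `voiclass` implements an atlas-driven analysis that turns
one PET volume per subject into a small vector of regional features and
asks how well a non-linear classifier separates patients with mild
cognitive impairment who later convert to dementia from healthy controls —
together with the full set of diagnostic-accuracy statistics a clinical
reader expects (sensitivity, specificity, likelihood ratios, diagnostic
odds ratio, ROC/AUC), and a voxel-wise t-sum abnormality score as a
comparator of the kind used by commercial single-scan tools.

Because patient scans cannot be redistributed, the package ships a
synthetic-cohort generator that reproduces the *statistical structure* the
analysis relies on; every stage is exercised and tested against it.

## From volumes to features

1. **VOI extraction.** A label volume assigns each voxel to one of 45
   bilateral regions (90 VOIs) plus bilateral cerebellar reference
   regions. The regional value is the arithmetic mean intensity over the
   region's voxels (`extract_voi_means()`); NaN voxels are excluded and
   counted, an all-NaN region is an error. Volumes must already be on the
   atlas grid — spatial normalization is out of scope.
2. **Cerebellar normalization.** Each regional mean is divided by the
   cerebellar reference (`normalize_to_cerebellum()`): the voxel-weighted
   mean over all cerebellar regions, i.e. the plain mean over their pooled
   voxel set. The cerebellum is relatively spared by the disease, so this
   removes injected-dose and scanner scaling without absorbing the
   disease signal. Whether the reference should instead be an unweighted
   mean of per-region means is not determined by convention; the pooled
   (weighted) reading is used and asserted by the tests.
3. **Meta-VOIs.** Twelve anatomo-functional groupings per hemisphere
   (occipital; thalamus/striatum; mesial temporal + insula; orbitofrontal;
   frontal; cuneus/fusiform/precuneus; sensorimotor; parietal; anterior
   cingulate; posterior cingulate; temporal; temporal pole) reduce 90
   regional values to 24. Merged values are voxel-count-weighted means, so
   merging commutes exactly with extraction over merged labels.
4. **Asymmetry indices.** For a bilateral (meta-)region with normalized
   values `nv_l`, `nv_r`, the asymmetry is `|nv_l - nv_r| / (nv_l + nv_r)`
   — dimensionless, in [0, 1], symmetric and scale-invariant. Meta-VOI
   asymmetries are computed from the merged left/right meta values, not by
   averaging constituent asymmetries, so a single formula serves both
   resolutions.
5. **Dataset variants.** `assemble_dataset()` builds the five analysis
   matrices: 90R, 24R, 90R+45A (135 features), 24R+12A (36 features), and
   arbitrary selected subsets. Cerebellar rows never become features.

## Gender correction

Control data show a region-by-gender interaction but no age effect in the
late-life age range studied; regional values are therefore adjusted for
gender only. `fit_gender_model()` fits, on controls only, a linear model
of value on region, gender, age and region x gender (long format) and
reports per-region offsets (female minus male cell means) plus screening
p-values. `apply_gender_correction()` subtracts from every subject the
control-estimated deviation of their gender from the pooled control mean —
identically for controls and patients, so the correction cannot leak group
information. Design notes:

* The correction is applied to regional values only. Asymmetry indices are
  ratios; subtracting an additive regional offset inside them would
  distort the index, so asymmetry features are computed from uncorrected
  values and left untouched.
* Within each gender stratum the control-versus-patient difference is
  preserved exactly (a constant is subtracted from every subject of a
  gender). Pooled group differences shift by (difference in gender mix) x
  (offset), which is precisely the confounding the adjustment removes.
* Re-applying a correction to an already corrected dataset is a no-op
  (the dataset is flagged), making the operation idempotent for a fixed
  model.
* Correction is fitted and applied at the resolution being classified
  (region-level for 90R variants, meta-level for 24R variants); both paths
  are available.

## Classification protocol

The classifier is a radial-basis-function support vector machine
(`e1071`/libsvm engine). Choices the original protocol leaves open are
fixed as follows, and recorded with every result:

* **Leave-one-out.** Each subject is scored by a model fitted to all
  remaining subjects. Features are standardized with training-fold
  statistics only; the held-out row is transformed with those statistics.
  The continuous decision value is kept (ROC construction needs it);
  label-flip tests assert that nothing derived from the held-out row
  reaches its own model.
* **Hyperparameters.** Cost 1; kernel width `1/d` on standardized features
  (`1/(d * pooled variance)` equivalently). An inner 5-fold grid search
  within each training fold is available (`svm_hyperparams(tune = TRUE)`)
  but off by default: at these sample sizes it mostly adds variance and
  run time.
* **Class weights.** Inverse-frequency class weights are applied in every
  fit. Leave-one-out folds are intrinsically imbalanced against the
  held-out class by one subject; unweighted fits acquire a systematic
  anti-bias that shows up as a heavy low tail in permutation-null
  accuracy. Balanced weights center the null at 0.5 and also counteract
  the 109:62 cohort imbalance.
* **Feature ranking.** Permutation importance: the LOO fold models are
  fitted once; a feature's importance is the mean drop in LOO accuracy
  when its column is permuted across subjects and every held-out subject
  is re-scored with its existing fold model (20 permutations by default,
  ties broken by feature order). Refitting per permutation would change
  nothing conceptually at three orders of magnitude more cost.
* **Backward elimination.** From the 36-feature meta dataset, the least
  important feature is removed one at a time; after each removal the LOO
  criterion (AUC by default, accuracy optionally) is recomputed. The
  returned subset maximizes the criterion along the trace, ties going to
  the smaller set. Two protocols are provided: *paper-faithful* (default)
  runs selection on the full sample's LOO criterion and then reports LOO
  metrics on the selected subset — optimistic, but the form in which such
  results are usually reported; *nested* (`loo_with_selection()`) repeats
  the selection inside every outer fold and is free of selection optimism.
  Reports label which was used.

## Diagnostic accuracy statistics

All statistics derive from the confusion counts at a threshold
(test-positive means score strictly greater; ties count negative):

* sensitivity/specificity/accuracy with Wald intervals
  (`p ± 1.96 sqrt(p(1-p)/n)`, clipped) or exact Clopper-Pearson intervals.
  The phrase "Wald interval with exact binomial probabilities" in the
  source literature is ambiguous; plain Wald reproduces the published
  accuracy interval but not every sensitivity bound, so both are
  implemented and neither is treated as ground truth.
* likelihood ratios `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec` with
  Simel log-normal intervals; zero cells yield infinite/zero ratios with
  flagged undefined intervals.
* diagnostic odds ratio `(TP*TN)/(FN*FP)` with the conventional
  log-transform interval; the Haldane-Anscombe 0.5 correction is available
  for zero cells but off by default.
* ROC over all distinct score thresholds; AUC by trapezoid, which equals
  the Mann-Whitney pair statistic with ties counted one half (asserted
  against brute-force pair counting). Bootstrap percentile intervals for
  the AUC use stratified within-class resampling.
* paired AUC comparison for two markers scored on the same subjects:
  DeLong-style placement components give the correlation-adjusted variance
  of the AUC difference; `z = (AUC_a - AUC_b)/SE`, one-sided p from the
  upper normal tail. A subject-bootstrap oracle and the independent pROC
  implementation guard this in the tests.
* the operating threshold is the ROC point closest (Euclidean) to
  (FPR 0, TPR 1), ties resolved toward higher specificity — the same rule
  used to re-threshold the comparator score in the original analysis.
* `reconstruct_confusion()` inverts printed 2-decimal rates to integer
  counts by exhaustive search with half-up rounding in exact integer
  arithmetic, erroring (and listing candidates) when the printed precision
  does not determine the counts uniquely. This enables the worked-example
  checks against the published performance table.

## The t-sum comparator

A simplified analog of commercial "probability of AD" scores: control
volumes (cerebellum-normalized, smoothed) define a per-voxel linear
regression of intensity on age; a subject's smoothed volume is converted
to a voxel-wise t-map `(expected - observed)/(sd * sqrt(1 + leverage))`,
positive where metabolism is below the age-adjusted expectation; the score
is the sum of t-values above a configurable floor (default 0) inside an
AD-pattern mask, and a scan is abnormal when the score exceeds a
threshold. The conventional fixed threshold 11,089 is kept as the
interface default for fidelity, but it is meaningless for phantoms, so
synthetic runs calibrate the threshold as the 95th percentile of held-out
null (control) scores. Residual SDs are floored at their own 10th
percentile to prevent t blow-ups at near-noiseless voxels. Whether the
original commercial score sums all positive t-values or only those above a
cutoff is not public; the floor is exposed as configuration without
asserting either behavior. This component is an analog for comparison
design purposes, not a reimplementation of any proprietary tool.

## The synthetic cohort

`cohort_spec()` defaults encode the study conditions: 109 controls
(57 women, ages 52-83) and 62 patients (34 women, ages 54-86). The
generative model for a voxel in region r of subject s is

```
value = scale_s * ( b_r * (1 - h_r)^[patient] * (1 - a_r)^[patient & left] + d_r^[female] ) + noise
```

with `b_r` the baseline (cerebellum-relative units, cerebellum = 1),
`h_r` the fractional hypometabolism, `a_r` the extra left-sided reduction,
`d_r` the gender offset, `scale_s ~ lognormal(0, 0.15)` an injected-dose
analog, and independent Gaussian voxel noise. Placing the gender offset
inside the global scale makes cerebellar normalization cancel the scale
exactly, so the fast feature-level path (`simulate_feature_cohort()`, with
region-level noise `voxel_sd/sqrt(voxels)`) agrees region-by-region with
extracting simulated volumes — an identity the tests assert at zero noise.
Each subject draws from its own RNG stream keyed by (seed, subject index),
so results are independent of generation order.

Default effect sizes are a package choice, not measured values: the
hypometabolism map (8-13% in precuneus, posterior cingulate,
temporo-parietal; 4-7% frontal/mesial-temporal) with left-predominant
extra reductions of 2-4% and voxel noise SD 1.8 (region-level SD 0.2) was
calibrated once so that the final classifier reaches leave-one-out
accuracy around .85-.90 and AUC around .90-.95 at the default cohort sizes
— the difficulty regime reported for real MCI-converter cohorts — and
frozen. The phantom is deliberately geometric: axis-aligned mirror-placed
regions, no partial-volume effects, no anatomical realism, independent
voxel noise. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not performance on real
scans; in real data regional noise is spatially correlated and effect
topography is subtler, so absolute accuracies here should not be read as
clinical claims.

## Numerical conventions and degenerate inputs

* Rounding against printed tables is half-up at 2 decimals, computed in
  integer arithmetic where exactness matters.
* Confusion ties at the threshold count as test-negative (strict
  inequality), everywhere.
* Constant feature columns get unit SD in fold standardization rather
  than dividing by zero.
* A degenerate (zero-variance) age vector in the t-sum reference drops the
  age term with a warning instead of failing.
* Single-class training folds, empty masks, non-positive cerebellar
  references, unknown region names and feature-space mismatches are all
  hard errors with the offending name in the message.

## Problem sizes used by the shipped runs

The demo configuration (`demo_run_config()`) runs 44 controls and 32
patients with 200 bootstrap replicates and 5 importance permutations —
the same effect structure at sizes chosen so a full two-invocation
determinism check completes in about a minute. The acceptance script runs
the full 109/62 study conditions with 1000 bootstrap replicates. The
vignette and README report only numbers those runs actually print.

## Known limitations

* The backward-selection default reports the optimistic (paper-faithful)
  protocol; use the nested mode for honest generalization estimates.
* The gender model assumes additive offsets; no site/center harmonization
  is attempted (centers entered the original voxel-level analysis only).
* The t-sum arm is a structural analog; its absolute scores are not
  comparable to any commercial tool's.
* Proportion-CI conventions in the source literature are not fully
  recoverable; both implemented variants are documented above.
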