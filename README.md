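# voiclass

Volume-of-interest (VOI) analysis of brain FDG-PET for discriminating
patients with amnestic mild cognitive impairment who convert to
Alzheimer-type dementia from healthy controls — for neuroimaging
methodologists and nuclear-medicine researchers who want the whole chain
(regional quantification → feature engineering → classifier →
diagnostic-accuracy statistics) as tested, reproducible code rather than a
one-off script.

## What it computes

Given volumes aligned to a labeled atlas (45 bilateral regions + cerebellar
references), or regional feature tables directly:

* **Regional features.** Mean uptake per VOI, normalized within subject to
  the pooled cerebellar mean; 12 bilateral anatomo-functional meta-VOIs
  (voxel-weighted merges); inter-hemispheric asymmetry indices

  `asy = |nv_L − nv_R| / (nv_L + nv_R)`

  and the dataset variants 90R, 24R, 90R+45A (135 features), 24R+12A
  (36 features) plus selected subsets. Regional values are adjusted for
  gender with offsets estimated on controls only.
* **Classification.** RBF-kernel SVM with leave-one-out cross-validation
  (per-fold standardization, inverse-frequency class weights), permutation
  feature importance, and stepwise backward elimination with a full
  criterion trace (optimistic full-sample and honest nested protocols).
* **Diagnostic accuracy.** Confusion counts at the ROC-optimal threshold
  (closest point to sensitivity = specificity = 1); sensitivity,
  specificity and accuracy with Wald or Clopper–Pearson intervals;
  likelihood ratios `LR+ = sens/(1−spec)`, `LR− = (1−sens)/spec` with
  Simel intervals; diagnostic odds ratio `(TP·TN)/(FN·FP)` with the
  log-transform interval; trapezoid/Mann–Whitney AUC with stratified
  bootstrap intervals; DeLong-style paired z-test for correlated AUCs;
  and exact reconstruction of integer confusion counts from printed
  2-decimal rates.
* **t-sum comparator.** A simplified voxel-wise abnormality score: age-
  adjusted per-voxel t-map of a subject against a control database, summed
  over an AD-pattern mask and thresholded (null-calibrated for phantoms).
* **Synthetic cohorts.** A phantom atlas builder and a two-group generator
  (109 controls / 62 patients by default, AD-like hypometabolism with
  left-predominant asymmetry, gender offsets, global-scale and voxel
  noise) so every stage above is testable without patient data.

## Worked example

```r
library(voiclass)

## published-table arithmetic: recover integer counts from printed rates
cm <- reconstruct_confusion(0.92, 0.91, n_pos = 62, n_neg = 109)
unlist(cm[c("TP", "FN", "FP", "TN")])
#> TP FN FP TN
#> 57  5 10 99
likelihood_ratios_with_ci(cm)$lr_plus
#>        est         lo         hi
#> 10.0209677  5.5257367 18.1731051
odds_ratio_with_ci(cm)
#>        est         lo         hi
#> 112.860000  36.754454 346.553366

## end-to-end synthetic study (reduced demo sizes; ~30 s)
rep <- run_pipeline(demo_run_config(seed = 1), out_dir = "demo_out")
```

The demo writes `report.json`, per-variant score CSVs, and a summary table
(`demo_out/summary.md`) with one column per dataset variant plus the t-sum
comparator:

```
# Classification summary (n = 44 controls, 32 patients, seed 1)

| measure     | 90R              | 24R              | 90R+45A          | 24R+12A          | 6R+6A               | tsum             |
| accuracy    | 0.84 (0.76-0.92) | 0.86 (0.78-0.93) | 0.75 (0.65-0.85) | 0.86 (0.78-0.93) | 0.93 (0.88-0.99)    | 0.59 (0.48-0.70) |
| sensitivity | 0.75 (0.60-0.90) | 0.84 (0.72-0.97) | 0.81 (0.68-0.95) | 0.91 (0.81-1.00) | 0.94 (0.85-1.00)    | 0.16 (0.03-0.28) |
| specificity | 0.91 (0.82-0.99) | 0.86 (0.76-0.97) | 0.70 (0.57-0.84) | 0.82 (0.70-0.93) | 0.93 (0.86-1.00)    | 0.91 (0.82-0.99) |
| lr_plus     | 8.25 (3.17-21.45)| 6.19 (2.90-13.21)| 2.75 (1.69-4.47) | 4.98 (2.64-9.42) | 13.75 (4.60-41.14)  | 1.72 (0.50-5.90) |
| lr_minus    | 0.28 (0.15-0.50) | 0.18 (0.08-0.41) | 0.27 (0.13-0.56) | 0.11 (0.04-0.34) | 0.07 (0.02-0.26)    | 0.93 (0.78-1.11) |
| odds_ratio  | 30.0 (8.2-110.4) | 34.2 (9.5-123.7) | 10.3 (3.4-31.0)  | 43.5 (10.6-178.9)| 205.0 (32.2-1303.9) | 1.85 (0.46-7.53) |
| auc         | 0.87 (0.79-0.95) | 0.92 (0.84-0.97) | 0.80 (0.69-0.89) | 0.91 (0.84-0.97) | 0.96 (0.92-0.99)    | 0.72 (0.61-0.82) |
```

Reading it: the backward-selection subset (`6R+6A`) discriminates best
(AUC .96), the full asymmetry-augmented regional set (`90R+45A`)
over-fits its 135 features at this sample size, and the voxel t-sum
comparator trails the VOI-based classifier — at its null-calibrated
threshold it is specific (.91) but insensitive (.16) at these reduced
demo sizes.

(Your numbers will match exactly at the same seed; the run is fully
deterministic.) The `6R+6A` column is the backward-selection variant: the
report also lists which meta-VOI values and asymmetries were retained. The
`comparisons` block holds the paired AUC z-tests of each variant against
the t-sum score.

At full study-condition sizes (109/62, `run_config()`), leave-one-out
accuracy lands around .85–.90 with AUC .90–.95 depending on variant and
seed — the difficulty regime the synthetic generator is calibrated to.

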