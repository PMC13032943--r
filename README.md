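# metabosig

Metabolic signature discovery for untargeted DI-MS metabolomics.

`metabosig` asks whether a clinical phenotype leaves a detectable trace in
plasma metabolomics measured by direct-infusion mass spectrometry (DI-MS),
and characterises that trace. It was built for the hardest common case:
surveillance cohorts with repeated visits per subject, technical
triplicates, day-of-run batch effects, a low-prevalence phenotype (such as
primary sclerosing cholangitis within IBD patients), and a treatment
confounder (such as ursodeoxycholic acid) concentrated in the cases.

The workflow, end to end:

1. **Preprocess** replicate-level peak tables: drop features missing in
   more than 20% of samples, quantile-normalise, impute (half-minimum),
   autoscale, centre out per-batch medians, average replicates.
2. **Split by subject** — an 80/20 holdout plus grouped stratified K-fold
   cross-validation, with a dual-variable scheme that spreads rare
   untreated cases one per fold (shrinking the fold count if needed).
3. **Classify** with per-fold random forests (`mtry = floor(sqrt(p))`),
   pooling out-of-fold scores into ROC/PR summaries, against a
   permuted-label negative control, compared by a paired DeLong test; a
   bootstrap subset test checks whether a subgroup's AUC is explained by
   its size.
4. **Rank features** by the combined V-score

   V = −log10(p) × log2(FC),

   with a Welch t-test p and the case/control fold change, ranked by |V|
   (or alternatively by the |z| of single-feature logistic regressions).
5. **Determine the signature size**: permute the top-k ranked features,
   retrain, and watch pooled AUROC fall with k against a random-feature
   arm and a label-shuffled arm; the elbow (flattest point) of the
   smoothed curve is the signature threshold.
6. **Enrich**: map the signature's m/z values to putative compounds via 19
   electrospray adduct rules and ppm matching, score metabolite sets with
   the conservative EASE hypergeometric tail (overlap minus one), split
   the signature by the sign of V, and build microbe metabolite-set
   databases from taxon–metabolite correlation tables (adjusted p < 0.05,
   positive correlation).

A first-class synthetic-cohort generator (`cohort_spec()`,
`generate_cohort()`, `generate_peak_table()`,
`generate_association_table()`) reproduces the full statistical structure
with a planted, recoverable truth, so everything is testable without any
patient data.

## Worked example

```r
library(metabosig)

spec <- cohort_spec(n_subjects = 100, n_features = 500, n_planted = 40,
                    planted_log2fc = 1, case_prevalence = 0.25, seed = 42)
meta <- generate_cohort(spec)
sim  <- generate_peak_table(meta, spec)
sim$peaks
#> peak_table: 543 replicate measurements (181 samples) x 500 m/z features [positive mode]
#>   m/z range: 71.4789 - 997.0393 Da; missing cells: 10.0%

pp <- preprocess_peaks(sim$peaks, meta)
pp
#> normalized_matrix: 181 samples x 500 features
#>   steps: filter_missing -> quantile_normalize -> impute_halfmin -> autoscale -> batch_center -> average_replicates

folds <- grouped_stratified_kfold(meta, "class_label", n_folds = 5, seed = 43)
rows  <- match(folds$sample_id, rownames(pp$scaled))
lab   <- meta$class_label[match(folds$sample_id, meta$sample_id)]

fit <- train_rf_cv(pp$scaled[rows, ], lab, folds$fold, n_trees = 200, seed = 44)
fit
#> model_eval: 181 pooled scores, AUROC 1.000, AUPRC 1.000 (positive = 1)

ctrl <- permuted_label_control(pp$scaled[rows, ], lab, folds$fold,
                               folds$subject_id, n_trees = 200, seed = 44)
ctrl
#> model_eval: 181 pooled scores, AUROC 0.427, AUPRC 0.180 (positive = 1)

delong_compare(fit$scores$score, ctrl$scores$score, fit$scores$label)
#> roc_comparison: AUC 1.000 vs 0.592, z = 7.755, one-sided p = 4.43e-15

rk <- rank_by_v(pp$intensity[rows, ], pp$scaled[rows, ], lab)
head(rk[order(rk$rank), c("mz", "p_value", "fold_change", "V", "rank")], 3)
#>           mz      p_value fold_change         V rank
#> 477 963.2550 1.017735e-08    2.390219 10.047543    1
#> 204 442.1634 3.660213e-07    2.287062  7.681927    2
#> 427 876.3099 2.999634e-08    1.966348  7.338762    3
```

Reading the output: the experimental model separates the planted phenotype
perfectly (pooled cross-validated AUROC 1.0) while the permuted-label
control sits at chance (0.427 against its own permuted labels); the DeLong
comparison of the two score vectors on the true labels is decisive
(p = 4.4e-15, `star_code()` gives `****`). The top-ranked m/z values carry
fold changes near the planted 2× with tiny p-values.

From there, `build_elimination_curves()` + `elbow_threshold()` give the
signature size, and `run_enrichment()` with a database from
`build_microbe_db()` tests metabolite sets; `run_pipeline()` chains all
eight stages and writes a manifest. See the vignette
(`vignettes/metabolic-signatures.Rmd`) for the full methods account.

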