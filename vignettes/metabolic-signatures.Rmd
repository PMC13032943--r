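---
title: "Metabolic signature discovery from DI-MS peak tables: methods and design"
author: "metabosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic signature discovery from DI-MS peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosig)
```

## What this package does

`metabosig` implements a complete workflow for asking whether a clinical
phenotype leaves a detectable trace in untargeted direct-infusion mass
spectrometry (DI-MS) plasma metabolomics, and for characterising that trace:

1. **Classify** -- cross-validated random-forest models score each sample's
   phenotype probability, with a permuted-label negative control.
2. **Rank** -- every m/z feature receives a univariate score combining
   statistical evidence and effect size.
3. **Threshold** -- stepwise permutation of the top-ranked features locates
   how many of them carry the bulk of the predictive signal (the
   *signature*).
4. **Interpret** -- the signature's m/z values are mapped, via adduct
   expansion, to putative compounds and tested for over-representation in
   metabolite sets: biochemical pathways, or sets of metabolites associated
   with individual gut microbial taxa.

The motivating application is distinguishing IBD patients with primary
sclerosing cholangitis (PSC-IBD) from IBD alone using plasma profiles from a
surveillance cohort: a low-prevalence phenotype (~8% of subjects), repeated
visits per subject, technical triplicates, day-of-run batches, and a
treatment confounder (ursodeoxycholic acid, UDCA) concentrated in the cases.
Every stage of the package is shaped by those four nuisances.

Because the package must be testable without access to any patient data, a
first-class synthetic-cohort generator reproduces exactly this structure
with a planted, recoverable truth.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` + `generate_peak_table()` simulate:

* **Subjects and visits.** Subjects carry a fixed binary phenotype drawn at
  prevalence `case_prevalence` (default 0.08, the subject-level prevalence
  of the motivating cohort), a sex, and a treatment flag set with
  probability `confounder_rate_in_cases` (default 0.82) for cases and never
  for controls. Visit counts are uniform on `visits_per_subject` (default
  1--3, matching a ~2.1 samples/subject surveillance cohort); the phenotype
  is constant across a subject's visits.
* **Intensities.** Feature baselines are log-normal (log2 SD 1.5 across
  features around a log2 mean of 17). Between-sample biological variation
  is `biological_sd` (log2 scale, default 0.8). The spec's field list needs
  such a parameter for any power statement to be meaningful; 0.8 makes a
  planted log2 fold change of 1 a detectable (power > 0.9 at ~100 subjects)
  but not trivial effect, which is the regime the workflow is designed for.
* **Planted effects.** `n_planted` features are multiplied by
  `2^planted_log2fc` in cases; the effect vector is recycled, so mixed-sign
  signatures can be planted. Optionally the planted features are placed at
  exact adduct m/z values (`planted_mz`) and further known masses can be
  added as non-differential `anchor_mz` features -- this is how end-to-end
  enrichment tests obtain a recoverable ground truth.
* **Technical structure.** Each sample is measured `replicate_count` times
  (default 3) with log2 replicate noise `replicate_noise_sd`; samples are
  injected in a randomised order and grouped into `batch_count` day-of-run
  batches, each contributing an additive per-feature log2 shift of SD
  `batch_shift_sd`.
* **Missingness.** Cells go missing with probability
  `min(1, 2 * missing_rate_base * (1 - u))` where `u` is the pooled
  intensity rank scaled to (0, 1): low-abundance censoring, the dominant
  DI-MS mechanism. The marginal rate equals `missing_rate_base` exactly for
  rates up to 0.5.
* **The m/z grid** is uniform on [70, 1000] Da with a 2 ppm minimum
  spacing, mirroring ppm-binned high-resolution peak tables. One ionisation
  mode is generated; the mode tag is carried for format fidelity only.

What the generator does *not* emulate: chromatographic or injection-order
drift, correlated metabolite modules, heavy-tailed intensity error,
phenotype onset during follow-up (class is fixed per subject), or any real
biochemistry outside the enrichment path (where real molecular formulas are
used). Passing tests therefore demonstrate that the machinery is correct
under the stated statistical structure, not that any particular biological
claim holds on real data.

## Preprocessing

`preprocess_peaks()` applies, in order: missingness filtering, quantile
normalisation, half-minimum imputation, autoscaling, per-batch median
centering, replicate averaging. The applied order is recorded in the
`provenance` field of the result.

* **Missingness filter.** A feature is removed iff *strictly more than*
  20% of samples have no signal (a feature missing in exactly 2 of 10
  samples survives). A sample counts as covered when at least one of its
  technical replicates recorded a signal; the replicate-versus-sample basis
  is a design choice recorded here, as is the strictness of the inequality.
* **Quantile normalisation** aligns each measurement's order statistics
  with the across-sample means of order statistics (ties get the mean of
  their tied quantiles). After it, all complete samples share one value
  multiset exactly.
* **Imputation.** Remaining missing cells become half the feature's
  minimum observed value -- the usual floor convention for values censored
  at the detection limit. Imputation runs before autoscaling so that both
  downstream matrices are complete (the forests require complete data).
* **Autoscaling** standardises each feature to mean 0, SD 1 (n - 1
  denominator). Constant features become all-zero and are flagged rather
  than fatal.
* **Batch correction** subtracts the per-feature batch median and restores
  the per-feature global median. This removes day-of-run location shifts
  while deliberately doing nothing else; injection order is carried in the
  metadata but unused. More aggressive multivariate corrections are out of
  scope, and on synthetic data location shifts are the whole batch effect.
* **Two output scales.** Statistical tests and classifiers consume the
  autoscaled matrix; fold changes are computed on the quantile-normalised,
  imputed *intensity* matrix, because a log2 ratio of mean-zero autoscaled
  values is undefined. Which scale feeds which statistic is a genuine
  design decision; per-feature t-test p-values are unaffected by the
  (linear) autoscaling, so only the fold-change scale matters.

## Splitting without leakage

Repeated visits make sample-level splits leak: the same subject's plasma
appearing in train and test folds inflates performance. All splitters
therefore assign *subjects*:

* `holdout_split()` reserves a fraction (default 20%) of subjects for
  enrichment, stratified on the class label -- and on the class x
  treatment interaction when a secondary variable is given, so rare
  untreated cases appear on both sides.
* `grouped_stratified_kfold()` greedily packs subjects (largest sample
  count first) into the fold with the fewest subjects of that class,
  breaking ties by total sample load. With unit subject weights this
  achieves the floor/ceiling-optimal per-fold class counts, which the test
  suite checks against the counting bound.
* `dual_variable_folds()` handles the treatment-confounded phenotype: the
  negative class is distributed by plain grouped K-fold, the positive class
  by grouped *stratified* K-fold on the treatment flag, and the fold count
  drops to the number of positive subjects in the rarest treatment
  category, so that (for example) four untreated cases force four folds
  with exactly one untreated case each. With no rare-category subject the
  scheme falls back to ordinary grouped stratification, with a warning.

`assert_grouped()` re-checks any plan programmatically; it runs inside the
pipeline on every plan produced.

## Classification and its controls

`train_rf_cv()` trains one probability forest per fold (ranger; `mtry =
floor(sqrt(n_features))`, i.e. the square root of the number of m/z values;
500 trees by default -- the forest default, since only `mtry` is prescribed
by the workflow) and scores each sample exactly once, by the fold that held
it out. ROC and PR curves are computed on the *pooled* out-of-fold scores.

AUROC is the Mann--Whitney rank statistic with ties counting one half;
AUPRC is stepwise precision-over-recall integration with tied scores
collapsed. Both are checked in the test suite against brute-force pair
counting.

Two null references are provided:

* `permuted_label_control()` re-runs the cross-validation with class labels
  permuted across subjects (all samples of a subject keep one permuted
  label) under the same fold plan.
* `delong_compare()` tests AUC(experimental) > AUC(control) with the paired
  DeLong variance; a zero-variance difference (identical scores) returns
  p = 1 with a degeneracy flag. p-values map to asterisks via
  `star_code()`, which deliberately has no double-asterisk tier.

`bootstrap_subset_test()` asks whether a subgroup's AUC (e.g. untreated
patients) is explained by its small size: it draws `n_boot` (default
10,000) matched-size subsets of the pooled test scores without replacement
(with-replacement is available behind a flag), redraws single-class
subsets, and runs a two-sided one-sample t-test of the bootstrap AUC
distribution against the observed subgroup AUC.

## Feature ranking

The V-score of a feature is

$$V = -\log_{10}(p) \times \log_2(\mathrm{FC}),$$

with `p` from a Welch two-sample t-test (Welch, because equal variances are
not defensible for metabolite intensities) and FC the case/control ratio of
means on the intensity scale. `V` is antisymmetric under fold-change
inversion and zero at FC = 1; features are ranked by descending `|V|`, ties
broken by smaller p then lower m/z. A p-value of exactly zero is clipped to
the smallest positive double and flagged; zero-variance features get p = 1,
V = 0.

`rank_by_logistic()` is the alternative criterion: a single-feature
logistic regression's Wald z, ranked by `|z|`. Perfect separation leaves
the ML z-value meaningless, so separating features are refit with a tiny
ridge penalty (1e-6 on the slope) and flagged. On one-feature-at-a-time
shift designs the two rankings agree strongly (Spearman rho > 0.8 in the
test suite), which is why either can feed the signature step.

`spearman_rank_agreement()` correlates two `|criterion|` vectors -- used to
check that two phenotypes (e.g. the clinical phenotype and sex) do not
induce confounded rankings before interpreting one of them.

Rankings are computed per fold on the fold's training samples for the
signature step, and once on the 20% holdout for enrichment, so feature
selection never sees its own evaluation data.

## Signature-size determination

`build_elimination_curves()` permutes, within each fold, the abundances of
that fold's top-k ranked features (permutation rather than removal: the
feature count, and hence `mtry` and model capacity, stays fixed), retrains
the fold models, and pools the out-of-fold scores -- over a grid of k with
two controls:

* a **random arm** permuting an accumulating random feature set of the same
  size, and
* a **label-shuffled arm**: models built with subject-level permuted labels.
  The shuffle here runs *within folds*, preserving each fold's class
  balance: a global permutation makes fold class proportions hypergeometric,
  and pooling the resulting miscalibrated fold scores biases the null AUROC
  visibly below 0.5 (~0.45 in our simulations) -- a structural artifact, not
  a property of chance-level prediction. Within-fold permutation keeps the
  control centred at 0.5 where a flat chance-level reference belongs.

The curve stops early once the ranked arm has been indistinguishable from
the shuffled arm (within `stop_tol` = 0.05 AUROC) for three consecutive
grid points -- but never before the five points the elbow detector needs.
Models are retrained from scratch at every grid point; coarse grids keep
this affordable.

`elbow_threshold()` finds where the ranked curve becomes flat. The curve is
smoothed by local-linear loess (tricube weights, span 0.75 by default --
the common plotting-smoother default; a span too small for the grid
disables smoothing, which is the right choice for noiseless constructed
curves). The derivative is taken by forward differences on the grid, and
the signature size is the *smallest* interior grid point whose absolute
derivative lies within 5% (of the derivative range) of the flattest
observed value. Treating near-flat points as tied and resolving toward
smaller k is essential: on any decline-then-flat curve the literal minimum
of `|dAUROC/dk|` sits arbitrarily deep in the flat tail and carries no
information about where flatness begins. The result is always a grid point
and is invariant to affine rescaling of the AUROC axis. A curve with less
than `min_decline` = 0.02 total decline raises a no-signal flag and reports
size 0.

## Enrichment

`run_enrichment()` interprets the signature without requiring compound
identification, in the style of m/z-level pathway enrichment:

* **Adducts.** `default_adducts()` ships 19 common electrospray rules
  (9 positive, 10 negative) with exact proton/electron bookkeeping;
  `formula_mass()` computes neutral monoisotopic masses over C, H, N, O, P,
  S, Na, K, Cl, F, Br, I, Se. The specific 19-rule table is a curated
  stand-in for whatever instrument-specific list a study uses, and is fully
  user-replaceable. Forward and inverse adduct arithmetic round-trip to
  1e-9 relative error.
* **Matching.** A compound matches when any adduct-predicted m/z is within
  `tolerance_ppm` (default 5 ppm, relative to the predicted m/z) of any
  query m/z. Many-to-many matches are kept in the match table; compounds
  are counted once per set. Raising the tolerance can only add matches.
* **Universe.** N is the number of database compounds matchable to the
  *full* measured feature list, not all database compounds -- enrichment is
  conditioned on detectability, otherwise undetectable set members dilute
  every test.
* **EASE score.** The hypergeometric upper tail at overlap k - 1 (the
  overlap penalised by one). This is deliberately conservative: singleton
  overlaps can never be significant. Significance is called at EASE
  p <= 0.05, inclusive.
* **Exclusions.** Sets whose names pair an essential amino acid
  (histidine, isoleucine, leucine, lysine, methionine, phenylalanine,
  threonine, tryptophan, valine) with "synthesis"/"biosynthesis" are
  removed before testing -- humans cannot run those pathways, so their
  enrichment would be an annotation artifact. Degradation sets are kept.
* **Directional analysis.** `split_by_sign()` partitions the signature by
  the sign of V (V > 0: relatively increased in cases), so enrichment can
  separately suggest increased and decreased metabolite sources; V = 0
  features belong to neither side and are counted.

`build_microbe_db()` turns a taxon--metabolite association table into
metabolite sets: rows survive iff the diversity-adjusted p-value is
strictly below 0.05, the correlation is positive, and a compound
identifier/formula is present; each taxon becomes one set, empty sets are
dropped. `generate_association_table()` synthesises such tables over a
built-in pool of real small-molecule formulas with a controllable fraction
of filter-passing rows.

## The orchestrated pipeline

`run_pipeline()` chains simulate, preprocess, split, train (+ control),
rank, signature, holdout rank and enrichment (all / V>0 / V<0), writing
every intermediate as plain text plus a JSON manifest with parameters,
seeds, package version and per-file checksums. Identical configurations
reproduce identical checksums. When `plant_taxon` is set, the planted
features are placed at [M+H]+ masses of the largest microbe set's
compounds, and all other database compounds enter the feature grid as
non-differential anchors, so the end-to-end run has a known enrichment
answer.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds; forests run
single-threaded with per-fold seeds, so every result in this package is
bit-reproducible. Simulation-based checks in the test suite use cohorts of
40--200 subjects and 50--2000 features, and the bundled acceptance script
runs a 150-subject, 800-feature cohort with a planted 0.7 log2FC effect on
60 features -- sizes chosen so the whole battery reproduces the workflow's
qualitative claims (signal/control separation, leakage-free splitting,
elbow recovery, enrichment recovery, DeLong calibration) on a laptop-class
machine.

## Known limitations

* Batch correction is location-only; real DI-MS drift can be
  multiplicative and time-ordered.
* The elimination curve retrains forests at every grid point; for
  tens of thousands of features use coarse grids first.
* EASE p-values are analytic; the empirical permutation variant of the
  enrichment algorithm is out of scope.
* The logistic ranking handles separation by ridge stabilisation, which
  caps rather than orders the separating features among themselves.
* One ionisation mode is modelled end to end; mode tags are carried but no
  mode-specific matching logic is applied.
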