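# shared fixture builders (all data generated in code at test time)

# small processed cohort: returns matrices aligned to a fold plan
small_cohort <- function(n_subjects = 60, n_features = 120, n_planted = 15,
                         planted_log2fc = 1.5, case_prevalence = 0.3,
                         n_folds = 4, seed = 11, ...) {
  spec <- cohort_spec(n_subjects = n_subjects, n_features = n_features,
                      n_planted = n_planted,
                      planted_log2fc = planted_log2fc,
                      case_prevalence = case_prevalence, seed = seed, ...)
  meta <- generate_cohort(spec)
  pt <- generate_peak_table(meta, spec)
  pp <- preprocess_peaks(pt$peaks, meta)
  folds <- grouped_stratified_kfold(meta, "class_label", n_folds,
                                    seed = seed + 1)
  rows <- match(folds$sample_id, rownames(pp$scaled))
  list(spec = spec, meta = meta, planted = pt$planted,
       x = pp$scaled[rows, , drop = FALSE],
       fc = pp$intensity[rows, , drop = FALSE],
       labels = meta$class_label[match(folds$sample_id, meta$sample_id)],
       folds = folds$fold, subjects = folds$subject_id, pp = pp)
}

# metadata-only cohort with controlled class/treatment subject counts
toy_meta <- function(n_controls, n_cases_treated, n_cases_untreated,
                     samples_per_subject = 2) {
  n <- n_controls + n_cases_treated + n_cases_untreated
  subj <- sprintf("S%03d", seq_len(n))
  cls <- rep(c(0L, 1L, 1L), c(n_controls, n_cases_treated, n_cases_untreated))
  trt <- rep(c(0L, 1L, 0L), c(n_controls, n_cases_treated, n_cases_untreated))
  nv <- rep_len(samples_per_subject, n)
  data.frame(
    sample_id = sprintf("%s_V%d", rep(subj, nv), unlist(lapply(nv, seq_len))),
    subject_id = rep(subj, nv),
    replicate_id = "R1",
    batch = "B01",
    class_label = rep(cls, nv),
    treatment = rep(trt, nv),
    stringsAsFactors = FALSE)
}

# brute-force AUROC by all-pairs counting (independent oracle)
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force hypergeometric tail P(X >= j) by direct enumeration
hyper_tail <- function(j, m, n, N) {
  jj <- max(j, max(0, m + n - N)):min(m, n)
  sum(choose(m, jj) * choose(N - m, n - jj)) / choose(N, n)
}

# tiny metabolite-set database over the built-in formula pool
toy_db <- function(n_sets = 5, set_size = 4, seed = 1) {
  set.seed(seed)
  pool <- builtin_formulas()
  n_cpd <- n_sets * set_size
  cpd <- data.frame(
    compound_id = sprintf("C%03d", seq_len(n_cpd)),
    formula = unname(pool[((seq_len(n_cpd) - 1) %% length(pool)) + 1]),
    stringsAsFactors = FALSE)
  sets <- split(cpd$compound_id, rep(sprintf("Set%02d", seq_len(n_sets)),
                                     each = set_size))
  metabolite_set_db(sets, cpd)
}
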