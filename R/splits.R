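# Subject-grouped data splitting ----------------------------------------

# collapse replicate/sample-level metadata to one row per sample
sample_level <- function(meta, cols) {
  smeta <- meta[!duplicated(meta$sample_id),
                c("sample_id", "subject_id", intersect(cols, colnames(meta))),
                drop = FALSE]
  missing_cols <- setdiff(cols, colnames(meta))
  if (length(missing_cols))
    stop_input("metadata lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  rownames(smeta) <- NULL
  smeta
}

# one row per subject with its label(s) and total sample count
subject_level <- function(smeta, label, secondary = NULL) {
  sub <- smeta[!duplicated(smeta$subject_id), , drop = FALSE]
  if (any(tapply(smeta[[label]], smeta$subject_id,
                 function(v) length(unique(v))) > 1L))
    stop_input("label '", label, "' varies within a subject")
  cnt <- table(smeta$subject_id)
  sub$n_samples <- as.integer(cnt[sub$subject_id])
  sub
}

#' Hold out an enrichment fraction, grouped by subject
#'
#' Assigns whole subjects (never individual samples) to either the
#' machine-learning fraction or the enrichment holdout, stratified on the
#' class label -- and, when `secondary` is given, on the label-secondary
#' interaction, so a rare treatment category inside the positive class is
#' spread across both fractions.
#'
#' @param meta Cohort metadata (replicate, sample or subject level).
#' @param label Name of the binary class column.
#' @param ml_fraction Fraction of subjects assigned to the ML set.
#' @param secondary Optional name of a secondary stratification column
#'   (e.g. treatment).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with `ml` and `holdout` (sample-level metadata subsets)
#'   and `plan`, a data frame (`sample_id`, `subject_id`, `assignment`)
#'   with assignment in `{"ml", "holdout"}`.
#' @export
holdout_split <- function(meta, label = "class_label", ml_fraction = 0.80,
                          secondary = NULL, seed = 1L) {
  check_probability(ml_fraction, "ml_fraction")
  smeta <- sample_level(meta, c(label, secondary))
  sub <- subject_level(smeta, label)
  cls <- table(sub[[label]])
  if (length(cls) != 2L || any(cls < 2L))
    stop_input("need at least 2 subjects per class for a holdout split")
  strata <- if (is.null(secondary)) {
    as.character(sub[[label]])
  } else paste(sub[[label]], sub[[secondary]], sep = "/")
  set.seed(as.integer(seed))
  ml_subjects <- character(0)
  for (s in sort(unique(strata))) {
    members <- sample(sub$subject_id[strata == s])
    ml_subjects <- c(ml_subjects, head(members, round(ml_fraction * length(members))))
  }
  assignment <- ifelse(smeta$subject_id %in% ml_subjects, "ml", "holdout")
  plan <- data.frame(sample_id = smeta$sample_id,
                     subject_id = smeta$subject_id,
                     assignment = assignment, stringsAsFactors = FALSE)
  list(ml = smeta[assignment == "ml", , drop = FALSE],
       holdout = smeta[assignment == "holdout", , drop = FALSE],
       plan = plan)
}

# greedy grouped assignment: subjects in decreasing sample-count order into
# the fold with (1) fewest subjects of the same stratum, (2) fewest total
# samples, (3) lowest index. With unit subject weights this attains the
# floor/ceiling-optimal per-stratum subject counts per fold.
greedy_grouped_assign <- function(sub, strata, n_folds) {
  ord <- order(-sub$n_samples, sample.int(nrow(sub)))
  fold_of <- setNames(integer(nrow(sub)), sub$subject_id)
  stratum_counts <- matrix(0L, n_folds, length(unique(strata)),
                           dimnames = list(NULL, unique(strata)))
  load <- numeric(n_folds)
  for (i in ord) {
    s <- strata[i]
    cand <- which(stratum_counts[, s] == min(stratum_counts[, s]))
    cand <- cand[load[cand] == min(load[cand])]
    f <- cand[1L]
    fold_of[sub$subject_id[i]] <- f
    stratum_counts[f, s] <- stratum_counts[f, s] + 1L
    load[f] <- load[f] + sub$n_samples[i]
  }
  fold_of
}

#' Grouped stratified K-fold assignment
#'
#' Assigns subjects (and thereby all their samples) to folds so that
#' per-fold class counts are as close as achievable to the global balance
#' -- the grouped analogue of stratified K-fold, preventing information
#' leakage from repeated sampling of one subject. If a class has fewer
#' subjects than `n_folds`, the fold count is reduced with a warning.
#'
#' @inheritParams holdout_split
#' @param n_folds Requested number of folds (>= 2).
#' @return A data frame (`sample_id`, `subject_id`, `fold`) with `fold` in
#'   `1..K`.
#' @export
grouped_stratified_kfold <- function(meta, label = "class_label",
                                     n_folds = 5, seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  smeta <- sample_level(meta, label)
  sub <- subject_level(smeta, label)
  cls <- table(sub[[label]])
  if (length(cls) < 2L) stop_input("need two classes to stratify")
  k <- min(n_folds, min(cls))
  if (k < 2L) stop_input("a class has fewer than 2 subjects")
  if (k < n_folds)
    warning(sprintf("reducing fold count from %d to %d (rarest class has %d subjects)",
                    n_folds, k, min(cls)))
  set.seed(as.integer(seed))
  fold_of <- greedy_grouped_assign(sub, as.character(sub[[label]]), k)
  data.frame(sample_id = smeta$sample_id, subject_id = smeta$subject_id,
             fold = unname(fold_of[smeta$subject_id]),
             stringsAsFactors = FALSE)
}

#' Dual-variable grouped fold assignment
#'
#' For treatment-confounded phenotypes: negative-class subjects are
#' distributed by grouped K-fold (balancing sample counts only), while
#' positive-class subjects are distributed by grouped *stratified* K-fold
#' on the secondary variable (e.g. treatment). The fold count is reduced
#' to the number of positive subjects in the rarest secondary category, so
#' every fold receives at least one such subject (e.g. four untreated
#' cases force four folds even when five were requested). With no
#' positive subject in a rare secondary category the scheme falls back to
#' [grouped_stratified_kfold()] on the label, with a warning.
#'
#' @inheritParams grouped_stratified_kfold
#' @param secondary Name of the secondary (treatment-like) column.
#' @param positive Value of `label` denoting the positive class; default
#'   is the second factor level.
#' @return A data frame (`sample_id`, `subject_id`, `fold`).
#' @export
dual_variable_folds <- function(meta, label = "class_label",
                                secondary = "treatment", n_folds = 5,
                                seed = 1L, positive = NULL) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  smeta <- sample_level(meta, c(label, secondary))
  sub <- subject_level(smeta, label)
  pos_lvl <- if (is.null(positive)) {
    positive_level(as_binary_factor(sub[[label]]))
  } else as.character(positive)
  pos <- sub[as.character(sub[[label]]) == pos_lvl, , drop = FALSE]
  neg <- sub[as.character(sub[[label]]) != pos_lvl, , drop = FALSE]
  sec_counts <- table(as.character(pos[[secondary]]))
  if (length(sec_counts) < 2L || min(sec_counts) < 2L) {
    warning("secondary variable has an empty or singleton category among ",
            "positive subjects; falling back to grouped_stratified_kfold")
    return(grouped_stratified_kfold(meta, label, n_folds, seed))
  }
  k <- min(n_folds, min(sec_counts))
  if (k < n_folds)
    message(sprintf("using %d folds rather than %d: only %d subjects in the rarest secondary category",
                    k, n_folds, min(sec_counts)))
  set.seed(as.integer(seed))
  fold_pos <- greedy_grouped_assign(pos, as.character(pos[[secondary]]), k)
  fold_neg <- greedy_grouped_assign(neg, rep("all", nrow(neg)), k)
  fold_of <- c(fold_pos, fold_neg)
  data.frame(sample_id = smeta$sample_id, subject_id = smeta$subject_id,
             fold = unname(fold_of[smeta$subject_id]),
             stringsAsFactors = FALSE)
}

#' Assert that a plan never splits a subject
#'
#' Programmatic leakage check: every subject must map to exactly one
#' assignment (fold or holdout side) in the plan.
#'
#' @param plan A data frame with `subject_id` and either `fold` or
#'   `assignment`.
#' @return Invisibly `TRUE`; errors if a subject spans assignments.
#' @export
assert_grouped <- function(plan) {
  col <- if ("fold" %in% colnames(plan)) "fold" else "assignment"
  n_per_subject <- tapply(plan[[col]], plan$subject_id,
                          function(v) length(unique(v)))
  if (any(n_per_subject > 1L))
    stop_input("subject(s) span multiple assignments: ",
               paste(names(n_per_subject)[n_per_subject > 1L], collapse = ", "))
  invisible(TRUE)
}
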