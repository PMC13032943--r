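# Random-forest cross-validation and ROC machinery ----------------------

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC; tied scores count one half.
#'
#' @param scores Numeric predicted scores (higher = more case-like).
#' @param labels Binary labels; the positive class is the second factor
#'   level (override with `positive`).
#' @param positive Optional value of `labels` denoting the positive class.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
auroc <- function(scores, labels, positive = NULL) {
  if (length(unique(labels)) < 2L)
    stop_input("AUROC undefined: only one class present")
  f <- as_binary_factor(labels, positive)
  pos <- f == positive_level(f)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_input("AUROC undefined: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of precision over recall increments, with tied
#' scores collapsed into a single threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels, positive = NULL) {
  if (length(unique(labels)) < 2L)
    stop_input("AUPRC undefined: only one class present")
  f <- as_binary_factor(labels, positive)
  pos <- f == positive_level(f)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_input("AUPRC undefined: only one class present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[block_end]
  fp <- cumsum(!y)[block_end]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(precision * diff(c(0, recall)))
}

#' Cross-validated random-forest evaluation
#'
#' Trains one probability forest per fold on the out-of-fold samples
#' (`mtry = floor(sqrt(n_features))`, the square root of the number of
#' m/z values) and scores each sample exactly once, by the model of the
#' fold holding it out. ROC and PR summaries are computed on the scores
#' pooled over all folds.
#'
#' @param x Numeric matrix, rows = samples (rownames = sample ids),
#'   columns = features.
#' @param labels Binary labels aligned with rows of `x`.
#' @param folds Integer fold id per row of `x` (e.g. from
#'   [grouped_stratified_kfold()] matched to rownames).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed threaded to forest construction per fold.
#' @param positive Optional positive-class value.
#' @return An object of class `model_eval`: list with `scores` (data
#'   frame: `sample_id`, `score`, `label`, `fold`), `auroc`, `auprc`,
#'   `n_trees`, `mtry`, `positive`.
#' @export
train_rf_cv <- function(x, labels, folds, n_trees = 500, seed = 1L,
                        positive = NULL) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x) || length(folds) != nrow(x))
    stop_input("'labels' and 'folds' must align with rows of 'x'")
  f <- as_binary_factor(labels, positive)
  pos_lvl <- positive_level(f)
  mtry <- floor(sqrt(ncol(x)))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  out <- vector("list", length(unique(folds)))
  for (k in seq_along(sort(unique(folds)))) {
    fk <- sort(unique(folds))[k]
    train <- folds != fk
    if (length(unique(f[train])) < 2L)
      stop_input(sprintf("training data for fold %s contains a single class", fk))
    fit <- ranger::ranger(x = x[train, , drop = FALSE], y = f[train],
                          num.trees = n_trees, mtry = mtry,
                          probability = TRUE, num.threads = 1L,
                          seed = as.integer(seed) + k)
    pr <- predict(fit, data = x[!train, , drop = FALSE],
                  num.threads = 1L)$predictions[, pos_lvl]
    out[[k]] <- data.frame(sample_id = ids[!train], score = pr,
                           label = as.character(f[!train]), fold = fk,
                           stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, out)
  structure(list(scores = scores,
                 auroc = auroc(scores$score, factor(scores$label, levels(f))),
                 auprc = auprc(scores$score, factor(scores$label, levels(f))),
                 n_trees = n_trees, mtry = mtry, positive = pos_lvl),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("model_eval: %d pooled scores, AUROC %.3f, AUPRC %.3f (positive = %s)\n",
              nrow(x$scores), x$auroc, x$auprc, x$positive))
  invisible(x)
}

#' Subject-level label permutation
#'
#' Permutes the subject-to-label map so that all samples of a subject
#' keep one common permuted label and subject-level class counts are
#' preserved exactly. With `within` (e.g. a fold id per sample), the
#' permutation additionally runs inside each stratum, preserving the
#' label balance of every fold of an existing plan -- this keeps a
#' permuted-label control free of the pessimistic bias that fold-level
#' class imbalance induces in pooled cross-validation scores.
#'
#' @param labels Label per sample.
#' @param subjects Subject id per sample.
#' @param seed Integer seed.
#' @param within Optional stratum (e.g. fold) per sample; must be
#'   constant within a subject.
#' @return Permuted label vector, same length and type as `labels`.
#' @export
permute_labels_by_subject <- function(labels, subjects, seed = 1L,
                                      within = NULL) {
  set.seed(as.integer(seed))
  usub <- unique(subjects)
  sub_lab <- labels[match(usub, subjects)]
  if (is.null(within)) {
    out <- sub_lab[sample.int(length(usub))]
  } else {
    sub_grp <- within[match(usub, subjects)]
    if (any(tapply(within, subjects, function(v) length(unique(v))) > 1L))
      stop_input("'within' must be constant within a subject")
    out <- sub_lab
    for (g in unique(sub_grp)) {
      idx <- which(sub_grp == g)
      out[idx] <- sub_lab[idx][sample.int(length(idx))]
    }
  }
  unname(setNames(out, usub)[as.character(subjects)])
}

#' Permuted-label negative control model
#'
#' Re-runs [train_rf_cv()] with class labels permuted across subjects
#' under the same fold assignment, giving the negative-control evaluation
#' the experimental model is compared against.
#'
#' @inheritParams train_rf_cv
#' @param subjects Subject id per row of `x`.
#' @return A `model_eval`, with the permuted labels in `scores$label` and
#'   an attribute `"permuted_labels"`.
#' @export
permuted_label_control <- function(x, labels, folds, subjects,
                                   n_trees = 500, seed = 1L,
                                   positive = NULL) {
  perm <- permute_labels_by_subject(labels, subjects, seed)
  ev <- train_rf_cv(x, perm, folds, n_trees = n_trees, seed = seed,
                    positive = positive)
  attr(ev, "permuted_labels") <- perm
  ev
}

#' Paired DeLong test for correlated ROC curves
#'
#' One-sided test of AUC(a) > AUC(b) for two score vectors over the same
#' samples and labels, using the DeLong variance of the paired AUC
#' difference. A degenerate zero-variance difference (e.g. identical
#' scores) returns statistic 0 and p = 1, flagged.
#'
#' @param scores_a,scores_b Score vectors over the same samples.
#' @param labels Binary labels.
#' @param positive Optional positive-class value.
#' @return An object of class `roc_comparison`: `auc_experimental`,
#'   `auc_control`, `statistic` (z), `p_value`, `sidedness`,
#'   `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_input("score vectors and labels must have equal length")
  f <- as_binary_factor(labels, positive)
  pos <- f == positive_level(f)
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop_input("both classes must be present")
  placements <- function(s) {
    X <- s[pos]; Y <- s[!pos]
    psi <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi),
         theta = mean(psi))
  }
  a <- placements(scores_a)
  b <- placements(scores_b)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$theta - b$theta
  degenerate <- !is.finite(v) || v <= .Machine$double.eps
  z <- if (degenerate) 0 else delta / sqrt(v)
  p <- if (degenerate) 1 else pnorm(z, lower.tail = FALSE)
  structure(list(auc_experimental = a$theta, auc_control = b$theta,
                 statistic = z, p_value = p, sidedness = "greater",
                 degenerate = degenerate),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("roc_comparison: AUC %.3f vs %.3f, z = %.3f, one-sided p = %.3g%s\n",
              x$auc_experimental, x$auc_control, x$statistic, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Significance star codes
#'
#' Encodes p-values as asterisks: `(0.01, 0.05] -> "*"`,
#' `(0.001, 0.01] -> "***"`, `p <= 0.001 -> "****"`, otherwise `""`.
#' (Note the deliberate absence of a double-asterisk tier.)
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star codes.
#' @export
#' @examples
#' star_code(c(0.5, 0.03, 0.005, 1e-4))
star_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must be in [0, 1]")
  ifelse(p <= 0.001, "****",
         ifelse(p <= 0.01, "***",
                ifelse(p <= 0.05, "*", "")))
}

#' Bootstrap test of subset performance against matched-size draws
#'
#' Compares the AUROC observed on a sample subset (e.g. untreated
#' patients) with the distribution of AUROCs over `n_boot` draws of the
#' same number of test samples from the pooled cross-validation scores.
#' Draws are without replacement by default; single-class draws are
#' redrawn. Significance is a two-sided one-sample t-test of the
#' bootstrap distribution against the observed subset AUC.
#'
#' @param eval A `model_eval` from [train_rf_cv()].
#' @param subset_ids Sample ids forming the subset (must contain both
#'   classes).
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @param replace Draw with replacement? Default `FALSE`.
#' @return An object of class `bootstrap_test`: `observed_auc`,
#'   `bootstrap_aucs`, `subset_size`, `p_value`.
#' @export
bootstrap_subset_test <- function(eval, subset_ids, n_boot = 10000,
                                  seed = 1L, replace = FALSE) {
  stopifnot(inherits(eval, "model_eval"))
  n_boot <- check_count(n_boot, "n_boot")
  sc <- eval$scores
  idx <- match(subset_ids, sc$sample_id)
  if (anyNA(idx)) stop_input("subset ids missing from pooled scores")
  if (length(idx) == 0L) stop_input("subset is empty")
  lab <- factor(sc$label)
  if (length(unique(sc$label[idx])) < 2L)
    stop_input("subset contains a single class")
  observed <- auroc(sc$score[idx], factor(sc$label[idx], levels(lab)),
                    positive = eval$positive)
  set.seed(as.integer(seed))
  s <- length(idx)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      draw <- sample.int(nrow(sc), s, replace = replace)
      if (length(unique(sc$label[draw])) == 2L) break
    }
    boot[b] <- auroc(sc$score[draw], factor(sc$label[draw], levels(lab)),
                     positive = eval$positive)
  }
  p <- if (sd(boot) == 0) {
    if (isTRUE(all.equal(mean(boot), observed))) 1 else 0
  } else t.test(boot, mu = observed)$p.value
  structure(list(observed_auc = observed, bootstrap_aucs = boot,
                 subset_size = s, p_value = p),
            class = "bootstrap_test")
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf(
    "bootstrap_test: observed AUC %.3f vs bootstrap mean %.3f (n = %d draws of %d), p = %.3g\n",
    x$observed_auc, mean(x$bootstrap_aucs), length(x$bootstrap_aucs),
    x$subset_size, x$p_value))
  invisible(x)
}
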