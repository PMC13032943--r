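test_that("AUROC matches the tie-aware pair-counting oracle and its conventions", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "one class")

  set.seed(10)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
  }
})

test_that("AUPRC integrates precision stepwise with tie handling", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores tied: a single block with precision = prevalence
  expect_equal(auprc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  # worst ranking of 1 positive among 4: precision 0.25 at recall 1
  expect_equal(auprc(c(4, 3, 2, 1), c(0, 0, 0, 1)), 0.25)
  expect_error(auprc(1:3, c(0, 0, 0)), "one class")
})

test_that("cross-validated forests score every sample once with sqrt-mtry", {
  cc <- small_cohort(n_subjects = 40, n_features = 100, n_planted = 20,
                     planted_log2fc = 2, case_prevalence = 0.4, seed = 17,
                     n_folds = 3)
  ev <- train_rf_cv(cc$x, cc$labels, cc$folds, n_trees = 80, seed = 1)
  expect_equal(ev$mtry, 10)  # floor(sqrt(100))
  expect_setequal(ev$scores$sample_id, rownames(cc$x))
  expect_equal(nrow(ev$scores), nrow(cc$x))
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  # strong planted signal should classify well
  expect_gt(ev$auroc, 0.85)
  # deterministic under seed
  ev2 <- train_rf_cv(cc$x, cc$labels, cc$folds, n_trees = 80, seed = 1)
  expect_identical(ev$scores, ev2$scores)

  bad_folds <- ifelse(cc$labels == 1, 1L, 2L)  # fold 2 trains on cases only
  expect_error(train_rf_cv(cc$x, cc$labels, bad_folds, n_trees = 10),
               "single class")
})

test_that("permuted-label controls preserve subject structure and destroy signal", {
  cc <- small_cohort(n_subjects = 40, n_features = 100, n_planted = 20,
                     planted_log2fc = 2, case_prevalence = 0.4, seed = 23,
                     n_folds = 3)
  perm <- permute_labels_by_subject(cc$labels, cc$subjects, seed = 4)
  expect_identical(perm, permute_labels_by_subject(cc$labels, cc$subjects,
                                                   seed = 4))
  # all samples of a subject share one permuted label
  expect_true(all(tapply(perm, cc$subjects,
                         function(v) length(unique(v))) == 1L))
  # subject-level class counts preserved exactly
  sub_orig <- cc$labels[!duplicated(cc$subjects)]
  sub_perm <- perm[!duplicated(cc$subjects)]
  expect_equal(sum(sub_perm), sum(sub_orig))
  expect_false(identical(sub_perm, sub_orig))

  ctrl <- permuted_label_control(cc$x, cc$labels, cc$folds, cc$subjects,
                                 n_trees = 80, seed = 4)
  expect_gt(ctrl$auroc, 0.3)
  expect_lt(ctrl$auroc, 0.7)
})

test_that("the DeLong comparison matches its contracts and independent oracles", {
  set.seed(6)
  labels <- rep(c(1, 0), each = 25)
  a <- ifelse(labels == 1, rnorm(50, 2), rnorm(50))
  b <- rnorm(50)

  same <- delong_compare(a, a, labels)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  fwd <- delong_compare(a, b, labels)
  rev <- delong_compare(b, a, labels)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_lt(fwd$p_value, 0.01)

  # permutation oracle: swap a/b within samples at random
  set.seed(7)
  obs <- fwd$auc_experimental - fwd$auc_control
  perm_delta <- replicate(400, {
    flip <- runif(50) < 0.5
    aa <- ifelse(flip, b, a); bb <- ifelse(flip, a, b)
    auroc(aa, labels) - auroc(bb, labels)
  })
  expect_lt(mean(perm_delta >= obs), 0.01)

  expect_error(delong_compare(a[-1], b, labels), "equal length")

  skip_if_not_installed("pROC")
  mk_roc <- function(s) pROC::roc(labels, s, quiet = TRUE, direction = "<",
                                  levels = c("0", "1"))
  pr <- pROC::roc.test(mk_roc(a), mk_roc(b), method = "delong",
                       alternative = "greater")
  expect_equal(fwd$statistic, unname(pr$statistic), tolerance = 1e-10)
  expect_equal(fwd$p_value, pr$p.value, tolerance = 1e-10)
})

test_that("star codes follow the asterisk convention with its skipped tier", {
  expect_equal(star_code(c(0.5, 0.06, 0.05, 0.03, 0.01, 0.005, 0.001, 1e-5)),
               c("", "", "*", "*", "***", "***", "****", "****"))
  expect_error(star_code(1.5), "\\[0, 1\\]")
})

test_that("the bootstrap subset test localises the observed AUC in the matched-size null", {
  # constructed pooled scores: clean separation overall
  set.seed(8)
  n <- 150
  labels <- rbinom(n, 1, 0.4)
  scores <- ifelse(labels == 1, rnorm(n, 1.7), rnorm(n))
  ev <- structure(list(
    scores = data.frame(sample_id = sprintf("S%03d", 1:n), score = scores,
                        label = labels, fold = 1L),
    auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    n_trees = 0, mtry = 0, positive = "1"), class = "model_eval")

  # a deliberately hard subset: worst-scored cases and best-scored controls
  hard <- c(order(ifelse(labels == 1, scores, Inf))[1:6],
            order(ifelse(labels == 0, -scores, Inf))[1:10])
  bt <- bootstrap_subset_test(ev, ev$scores$sample_id[hard], n_boot = 800,
                              seed = 2)
  expect_equal(bt$subset_size, 16)
  expect_lt(bt$observed_auc, mean(bt$bootstrap_aucs) - 0.15)
  expect_lt(bt$p_value, 0.001)
  # deterministic
  bt2 <- bootstrap_subset_test(ev, ev$scores$sample_id[hard], n_boot = 800,
                               seed = 2)
  expect_identical(bt$bootstrap_aucs, bt2$bootstrap_aucs)

  # observed equal to the bootstrap mean: p near 1
  whole <- bootstrap_subset_test(ev, ev$scores$sample_id, n_boot = 300,
                                 seed = 3)
  expect_gt(whole$p_value, 0.9)

  one_class <- which(labels == 1)[1:5]
  expect_error(bootstrap_subset_test(ev, ev$scores$sample_id[one_class], 10),
               "single class")
})
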