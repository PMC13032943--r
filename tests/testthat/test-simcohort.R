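test_that("cohort generation is deterministic and respects the spec", {
  spec <- cohort_spec(n_subjects = 200, n_features = 20, n_planted = 0,
                      seed = 42)
  m1 <- generate_cohort(spec)
  m2 <- generate_cohort(spec)
  expect_identical(m1, m2)

  # exactly replicate_count rows per sample
  expect_true(all(table(m1$sample_id) == spec$replicate_count))
  # replicates of a sample share subject, batch and labels
  for (col in c("subject_id", "batch", "class_label", "sex", "treatment")) {
    expect_true(all(tapply(m1[[col]], m1$sample_id,
                           function(v) length(unique(v))) == 1L))
  }
  # class fixed per subject, treatment only in cases
  expect_true(all(tapply(m1$class_label, m1$subject_id,
                         function(v) length(unique(v))) == 1L))
  expect_true(all(m1$treatment[m1$class_label == 0] == 0))
})

test_that("subject-level class and treatment rates match the spec within binomial error", {
  spec <- cohort_spec(n_subjects = 1000, n_features = 5, n_planted = 0,
                      case_prevalence = 0.08,
                      confounder_rate_in_cases = 0.82, seed = 7)
  meta <- generate_cohort(spec)
  sub <- meta[!duplicated(meta$subject_id), ]
  p_hat <- mean(sub$class_label)
  se <- sqrt(0.08 * 0.92 / 1000)
  expect_lt(abs(p_hat - 0.08), 3 * se)
  cases <- sub[sub$class_label == 1, ]
  se_t <- sqrt(0.82 * 0.18 / nrow(cases))
  expect_lt(abs(mean(cases$treatment) - 0.82), 3 * se_t)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(case_prevalence = 1.2), "probability")
  expect_error(cohort_spec(n_planted = 50, n_features = 10), "n_planted")
  expect_error(cohort_spec(replicate_count = 0), "replicate_count")
})

test_that("planted features carry the requested log2 effect", {
  spec <- cohort_spec(n_subjects = 300, visits_per_subject = 1,
                      case_prevalence = 0.5, n_features = 40,
                      n_planted = 10, planted_log2fc = 1,
                      replicate_count = 1, missing_rate_base = 0,
                      batch_shift_sd = 0, seed = 5)
  meta <- generate_cohort(spec)
  pt <- generate_peak_table(meta, spec)
  lg <- log2(pt$peaks$intensities)
  case <- meta$class_label == 1
  diff_means <- colMeans(lg[case, ]) - colMeans(lg[!case, ])
  # geometric-mean ratio ~ 2 for planted features, ~ 1 elsewhere
  expect_true(all(abs(diff_means[pt$planted] - 1) < 0.35))
  expect_true(all(abs(diff_means[-pt$planted]) < 0.35))
})

test_that("a null cohort plants no signal and zero missing rate means none", {
  spec <- cohort_spec(n_subjects = 100, visits_per_subject = 1,
                      case_prevalence = 0.5, n_features = 100,
                      n_planted = 0, replicate_count = 1,
                      missing_rate_base = 0, seed = 9)
  meta <- generate_cohort(spec)
  pt <- generate_peak_table(meta, spec)
  expect_false(anyNA(pt$peaks$intensities))
  lg <- log2(pt$peaks$intensities)
  case <- meta$class_label == 1
  p <- apply(lg, 2, function(v) t.test(v[case], v[!case])$p.value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-3)
})

test_that("missingness is calibrated to the marginal target and favours low intensities", {
  spec <- cohort_spec(n_subjects = 150, n_features = 100, n_planted = 0,
                      missing_rate_base = 0.2, seed = 13)
  meta <- generate_cohort(spec)
  pt <- generate_peak_table(meta, spec)
  x <- pt$peaks$intensities
  expect_lt(abs(mean(is.na(x)) - 0.2), 0.01)
  # low-abundance features are censored more than high-abundance ones
  med <- apply(x, 2, median, na.rm = TRUE)
  miss <- colMeans(is.na(x))
  lo <- miss[med < quantile(med, 0.25)]
  hi <- miss[med > quantile(med, 0.75)]
  expect_gt(mean(lo), mean(hi))
})

test_that("m/z grids respect positivity, uniqueness, 2 ppm spacing and fixed masses", {
  spec <- cohort_spec(n_subjects = 5, n_features = 500, n_planted = 10,
                      seed = 3)
  meta <- generate_cohort(spec)
  fixed <- c(101.003, 250.5004, 799.99)
  pt <- generate_peak_table(meta, spec, planted_mz = fixed,
                            anchor_mz = c(333.3, 444.4))
  mz <- pt$peaks$mz
  expect_true(all(mz > 0))
  expect_false(anyDuplicated(mz) > 0)
  expect_true(all(diff(mz) >= 2e-6 * mz[-length(mz)]))
  expect_true(all(fixed %in% mz))
  expect_true(all(c(333.3, 444.4) %in% mz))
  expect_true(all(fixed %in% mz[pt$planted]))
})

test_that("association tables are reproducible with a controllable significant fraction", {
  a1 <- generate_association_table(30, 50, frac_significant = 0.5, seed = 2)
  a2 <- generate_association_table(30, 50, frac_significant = 0.5, seed = 2)
  expect_identical(a1, a2)
  pass <- a1$p_adjusted < 0.05 & a1$rho > 0
  se <- sqrt(0.25 / nrow(a1))
  expect_lt(abs(mean(pass) - 0.5), 4 * se)

  a0 <- generate_association_table(30, 50, frac_significant = 0, seed = 2)
  expect_equal(length(build_microbe_db(a0)$sets), 0)
})

test_that("planted effects at log2FC 1 are detectable with high power at 100+ subjects", {
  spec <- cohort_spec(n_subjects = 120, n_features = 300, n_planted = 20,
                      planted_log2fc = 1, seed = 21)
  meta <- generate_cohort(spec)
  pt <- generate_peak_table(meta, spec)
  pp <- preprocess_peaks(pt$peaks, meta)
  retained <- match(sprintf("%.6f", pt$peaks$mz[pt$planted]),
                    colnames(pp$scaled))
  retained <- retained[!is.na(retained)]
  smeta <- meta[!duplicated(meta$sample_id), ]
  case <- smeta$class_label[match(rownames(pp$scaled), smeta$sample_id)] == 1
  p <- apply(pp$scaled[, retained, drop = FALSE], 2,
             function(v) t.test(v[case], v[!case])$p.value)
  expect_gt(mean(p < 0.05), 0.9)
})
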