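make_pt <- function(x, sample_id = sprintf("S%02d", seq_len(nrow(x))),
                    replicate_id = "R1",
                    mz = seq_len(ncol(x)) + 100) {
  peak_table(x, sample_id, rep_len(replicate_id, nrow(x)), mz)
}

test_that("the missingness filter keeps 20%-missing features and drops worse, at sample level", {
  x <- matrix(10, nrow = 10, ncol = 3)
  x[1:2, 1] <- NA   # 2 of 10 samples missing -> retained
  x[1:3, 2] <- NA   # 3 of 10 samples missing -> removed
  pt <- make_pt(x)
  filt <- filter_missing(pt, 0.20)
  expect_equal(length(filt$mz), 2L)
  expect_false(102 %in% filt$mz)
  expect_equal(attr(filt, "removed")$mz, 102)
  expect_equal(attr(filt, "removed")$frac_missing, 0.3)

  # a sample counts as present when any replicate has a signal
  x2 <- matrix(10, nrow = 6, ncol = 1)
  x2[c(1, 3, 5), 1] <- NA
  pt2 <- peak_table(x2, rep(c("A", "B", "C"), each = 2),
                    rep(c("R1", "R2"), 3), mz = 100)
  expect_equal(length(filter_missing(pt2, 0)$mz), 1L)

  # monotone: lowering the threshold never retains more features
  set.seed(1)
  x3 <- matrix(runif(200), 20, 10)
  x3[sample(200, 60)] <- NA
  pt3 <- make_pt(x3)
  n_kept <- vapply(c(0, 0.1, 0.2, 0.5, 1),
                   function(th) length(filter_missing(pt3, th)$mz),
                   numeric(1))
  expect_true(all(diff(n_kept) >= 0))
})

test_that("filter_missing rejects empty tables", {
  x <- matrix(1, 2, 2)
  pt <- make_pt(x)
  pt$intensities <- pt$intensities[, 0, drop = FALSE]
  pt$mz <- numeric(0)
  expect_error(filter_missing(pt), "empty")
})

test_that("quantile normalisation aligns order statistics across samples", {
  m <- rbind(c(1, 3, 5), c(2, 4, 8))
  qn <- quantile_normalize(m)
  expect_equal(qn[1, ], c(1.5, 3.5, 6.5))
  expect_equal(qn[2, ], c(1.5, 3.5, 6.5))

  # identical samples unchanged; single sample unchanged
  same <- rbind(c(2, 7, 1), c(2, 7, 1))
  expect_equal(quantile_normalize(same), same)
  one <- matrix(c(9, 1, 4), 1)
  expect_equal(quantile_normalize(one), one)

  # complete samples share one value multiset exactly
  set.seed(4)
  big <- matrix(rlnorm(300), 10, 30)
  qn2 <- quantile_normalize(big)
  ref <- sort(qn2[1, ])
  for (i in 2:10) expect_equal(sort(qn2[i, ]), ref, tolerance = 1e-12)
})

test_that("autoscaling centres and scales features, handling constants and idempotence", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- autoscale(m)
  expect_equal(unname(sc[, "a"]), c(-1, 0, 1))
  expect_equal(unname(sc[, "b"]), c(0, 0, 0))
  expect_equal(unname(attr(sc, "constant_features")), c(FALSE, TRUE))
  expect_equal(autoscale(sc)[, "a"], sc[, "a"])

  set.seed(2)
  m2 <- matrix(rnorm(200, 5, 3), 20, 10)
  sc2 <- autoscale(m2)
  expect_true(all(abs(colMeans(sc2)) < 1e-8))
  expect_true(all(abs(apply(sc2, 2, sd) - 1) < 1e-8))
})

test_that("batch centering equalises batch medians and preserves the global median", {
  set.seed(3)
  m <- matrix(rnorm(60), 12, 5)
  batch <- rep(c("b1", "b2"), each = 6)
  shifted <- m
  shifted[batch == "b2", ] <- shifted[batch == "b2", ] + 1
  fixed <- batch_center(shifted, batch)
  for (j in 1:5) {
    expect_equal(median(fixed[batch == "b1", j]),
                 median(fixed[batch == "b2", j]))
    expect_equal(median(fixed[, j]), median(shifted[, j]))
  }
  # single batch: unchanged
  expect_equal(batch_center(m, rep("b1", 12)), m)
  expect_error(batch_center(m, rep(NA, 12)), "batch")
  expect_error(batch_center(m, "b1"), "one label per row")
})

test_that("replicate averaging uses present values and propagates all-missing", {
  x <- rbind(c(1, 4, NA), c(2, NA, NA), c(3, 6, NA))
  out <- average_replicates(x, rep("S1", 3))
  expect_equal(unname(out[1, ]), c(2, 5, NA))
  expect_error(average_replicates(x, c("a", "b")), "one entry per row")
})

test_that("half-minimum imputation floors missing cells below observed values", {
  x <- cbind(c(4, NA, 8), c(NA, NA, NA))
  imp <- impute_halfmin(x)
  expect_equal(imp[2, 1], 2)
  expect_true(all(is.na(imp[, 2])))
})

test_that("the full preprocessing pipeline records provenance and returns both scales", {
  cc <- small_cohort(n_subjects = 30, n_features = 40, n_planted = 5,
                     seed = 8)
  pp <- cc$pp
  expect_equal(pp$provenance,
               c("filter_missing", "quantile_normalize", "impute_halfmin",
                 "autoscale", "batch_center", "average_replicates"))
  expect_true(all(pp$intensity > 0))
  expect_false(anyNA(pp$scaled))
  expect_equal(rownames(pp$scaled), rownames(pp$intensity))
  expect_error(preprocess_peaks(
    generate_peak_table(generate_cohort(cc$spec), cc$spec)$peaks,
    cc$meta[0, ]), "metadata")
})
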