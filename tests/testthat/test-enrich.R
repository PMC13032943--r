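test_that("formula masses match IUPAC monoisotopic summation", {
  expect_equal(formula_mass("H2O"), 18.010565, tolerance = 1e-5)
  expect_equal(formula_mass("C6H12O6"), 180.063388, tolerance = 1e-5)
  expect_equal(formula_mass("CHNOPS"),
               12 + 1.0078250319 + 14.0030740052 + 15.9949146221 +
                 30.97376151 + 31.97207069, tolerance = 1e-9)
  expect_error(formula_mass(""), "empty")
  expect_error(formula_mass("X5"), "unknown element")
  expect_error(formula_mass("C6h12"), "malformed|unknown")
  # every built-in formula parses to a positive mass
  masses <- formula_mass(builtin_formulas())
  expect_true(all(masses > 0))
})

test_that("adduct arithmetic reproduces proton-mass bookkeeping", {
  rules <- default_adducts()
  expect_equal(nrow(rules), 19L)
  get <- function(nm) rules[rules$name == nm, ]
  expect_equal(unname(adduct_mz(100, get("[M+H]+"))), 101.007276,
               tolerance = 1e-6)
  expect_equal(unname(adduct_mz(100, get("[M-H]-"))), 98.992724,
               tolerance = 1e-6)
  expect_equal(unname(adduct_mz(100, get("[2M+H]+"))), 201.007276,
               tolerance = 1e-6)
  expect_equal(unname(adduct_mz(100, get("[M+2H]2+"))), 51.007276,
               tolerance = 1e-6)
  expect_error(adduct_mz(-5), "positive")
})

test_that("adduct forward/inverse is the identity for every rule", {
  rules <- default_adducts()
  set.seed(12)
  masses <- runif(50, 60, 900)
  for (r in seq_len(nrow(rules))) {
    for (M in masses) {
      mz <- unname(adduct_mz(M, rules[r, , drop = FALSE]))
      back <- neutral_candidates(mz, rules[r, , drop = FALSE])$neutral_mass
      expect_lt(abs(back - M) / M, 1e-9)
    }
  }
})

test_that("ppm matching respects the tolerance boundary and monotonicity", {
  db <- toy_db(n_sets = 2, set_size = 3)
  m <- db$compounds$mass[1]
  pred <- unname(adduct_mz(m, default_adducts()[1, ]))  # [M+H]+

  exact <- match_signature(pred, db, tolerance_ppm = 0)
  expect_true(db$compounds$compound_id[1] %in% exact$compounds)

  off <- pred * (1 + 5.5e-6)   # 5.5 ppm away
  m5 <- match_signature(off, db, tolerance_ppm = 5)
  expect_false(db$compounds$compound_id[1] %in% m5$compounds)
  m6 <- match_signature(off, db, tolerance_ppm = 6)
  expect_true(db$compounds$compound_id[1] %in% m6$compounds)

  # increasing tolerance never loses matches
  set.seed(9)
  queries <- runif(60, 80, 600)
  sizes <- vapply(c(0, 1, 5, 20, 100), function(tol)
    length(match_signature(queries, db, tolerance_ppm = tol)$compounds),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(match_signature(100, db, rules = data.frame()), "adduct rules")
})

test_that("the EASE score equals the overlap-minus-one hypergeometric tail", {
  expect_equal(ease_test(0, 10, 100, 1000), 1)
  expect_equal(ease_test(1, 10, 100, 1000), 1)
  expect_equal(ease_test(5, 10, 100, 1000), hyper_tail(4, 10, 100, 1000),
               tolerance = 1e-12)
  expect_error(ease_test(5, 3, 100, 1000), "inconsistent")
  expect_error(ease_test(2, 10, 100, 5), "inconsistent")

  set.seed(14)
  for (i in 1:100) {
    N <- sample(5:60, 1)
    m <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(max(0, m + n - N):min(m, n), 1)
    expect_equal(ease_test(k, m, n, N),
                 if (k <= 1) 1 else hyper_tail(k - 1, m, n, N),
                 tolerance = 1e-12)
  }
})

test_that("the signature splits cleanly by V sign", {
  rk <- data.frame(mz = c(100, 200, 300, 400, 500),
                   V = c(2, -1, 0, 3, -4), rank = c(2, 4, 5, 1, 3))
  sp <- split_by_sign(rk, 4)
  expect_setequal(sp$v_pos, c(100, 400))
  expect_setequal(sp$v_neg, c(200, 500))
  expect_equal(sp$n_zero, 0)
  sp5 <- split_by_sign(rk, 5)  # now includes the V = 0 feature
  expect_equal(length(sp5$v_pos) + length(sp5$v_neg) + sp5$n_zero, 5)
  expect_equal(sp5$n_zero, 1)
  all_pos <- data.frame(mz = 1:3 + 100, V = c(1, 2, 3), rank = 3:1)
  expect_length(split_by_sign(all_pos, 3)$v_neg, 0)
})

test_that("essential amino-acid biosynthesis sets are excluded but degradation kept", {
  expect_true(is_excluded_set("Lysine biosynthesis"))
  expect_true(is_excluded_set("VALINE BIOSYNTHESIS II"))
  expect_true(is_excluded_set("Tryptophan synthesis"))
  expect_false(is_excluded_set("Lysine degradation"))
  expect_false(is_excluded_set("Arginine and proline metabolism"))
  expect_false(is_excluded_set("Fatty acid biosynthesis"))
})

test_that("microbe database construction applies the strict significance filter", {
  assoc <- data.frame(
    taxon = c("A", "A", "B", "B", "C", "C"),
    compound_id = c("c1", "c2", "c3", "", "c5", "c6"),
    formula = c("C6H12O6", "H2O", "C3H6O3", "C2H4O2", NA, "C4H8O2"),
    rho = c(0.4, -0.3, 0.5, 0.6, 0.7, 0.2),
    p_adjusted = c(0.04, 0.001, 0.05, 0.01, 0.01, 0.049))
  db <- build_microbe_db(assoc)
  # A keeps only c1 (c2 has negative rho); B loses c3 (p = 0.05, strict)
  # and the id-less row; C loses the formula-less row but keeps c6
  expect_setequal(names(db$sets), c("A", "C"))
  expect_equal(db$sets$A, "c1")
  expect_equal(db$sets$C, "c6")
  expect_equal(db$compounds$mass[db$compounds$compound_id == "c1"],
               formula_mass("C6H12O6"))
  expect_error(build_microbe_db(assoc[, -1]), "lacks column")
})

test_that("GMT round-trip preserves sets and compound masses", {
  db <- toy_db(n_sets = 3, set_size = 4)
  path <- file.path(tempdir(), "sets.gmt")
  write_gmt(db, path)
  back <- read_gmt(path)
  expect_equal(back$sets, db$sets)
  expect_equal(back$compounds$mass, db$compounds$mass, tolerance = 1e-9)
})

test_that("enrichment flags a planted set and keeps nulls mostly quiet", {
  set.seed(33)
  db <- toy_db(n_sets = 12, set_size = 6, seed = 33)
  planted_set <- db$sets[["Set01"]]
  proton <- default_adducts()$mass_shift[1]
  planted_mz <- db$compounds$mass[match(planted_set,
                                        db$compounds$compound_id)] + proton
  decoy_mz <- runif(400, 70, 900)
  other_mz <- db$compounds$mass[!db$compounds$compound_id %in% planted_set] +
    proton
  # universe: planted masses first, then unmatchable decoys, then the
  # remaining compounds' masses (detectable but outside the signature)
  universe_mz <- c(planted_mz, decoy_mz, other_mz)
  n <- length(universe_mz)
  ranked <- data.frame(mz = universe_mz,
                       V = c(rep(2, length(planted_mz)),
                             rep(0.1, n - length(planted_mz))),
                       rank = seq_len(n))
  res <- run_enrichment(ranked, n_signature = 40, db)
  expect_true(res$significant[res$set == "Set01"])
  expect_lt(res$ease_p[res$set == "Set01"], 0.05)
  expect_gt(mean(!res$significant[res$set != "Set01"]), 0.8)
  expect_true(all(res$k <= pmin(res$m, res$n)))
  # signature of unmatchable decoys only: every set has k = 0 and p = 1
  ranked_dec <- ranked
  decoy_rows <- seq(length(planted_mz) + 1, length.out = length(decoy_mz))
  ranked_dec$rank[decoy_rows] <- seq_along(decoy_rows)
  ranked_dec$rank[-decoy_rows] <- length(decoy_rows) +
    seq_len(n - length(decoy_rows))
  res0 <- run_enrichment(ranked_dec, n_signature = 5, db)
  expect_true(all(res0$k == 0))
  expect_true(all(res0$ease_p == 1))
})
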