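# Mummichog-style metabolite-set enrichment -----------------------------

# monoisotopic masses of the lightest isotopes (Da)
MONOISOTOPIC <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637069,
  Cl = 34.96885271, F = 18.9984032, Br = 78.9183376, I = 126.904468,
  Se = 79.9165218)
ELECTRON_MASS <- 0.00054857990924
PROTON_MASS <- 1.00727646688

#' Monoisotopic mass of a molecular formula
#'
#' Parses an element-count formula string (e.g. `"C6H12O6"`) over the
#' built-in monoisotopic mass table (C, H, N, O, P, S, Na, K, Cl, F, Br,
#' I, Se) and returns the neutral monoisotopic mass in Da.
#'
#' @param formula Character vector of formulas.
#' @return Numeric vector of masses (Da).
#' @export
#' @examples
#' formula_mass("H2O")      # 18.010565
#' formula_mass("C6H12O6")  # 180.063388
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) stop_input("empty formula")
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (!length(parts) || sum(nchar(parts)) != nchar(f))
      stop_input("malformed formula: ", f)
    mass <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      cnt <- sub("^[A-Za-z]+", "", p)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% names(MONOISOTOPIC))
        stop_input("unknown element '", el, "' in formula: ", f)
      mass <- mass + MONOISOTOPIC[[el]] * cnt
    }
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default electrospray adduct rules
#'
#' Nineteen common ESI adducts (nine positive, ten negative), each
#' defined by a multimer count, a total mass shift (including
#' proton/electron bookkeeping) and a signed charge. The observed m/z of
#' a neutral mass M under a rule is
#' `(multimer * M + mass_shift) / |charge|`. The table is plain data and
#' fully user-replaceable.
#'
#' @return Data frame with columns `name`, `multimer`, `mass_shift`,
#'   `charge`, `mode`.
#' @export
default_adducts <- function() {
  H <- MONOISOTOPIC[["H"]]; N <- MONOISOTOPIC[["N"]]
  C <- MONOISOTOPIC[["C"]]; O <- MONOISOTOPIC[["O"]]
  water <- 2 * H + O
  acn <- 2 * C + 3 * H + N          # acetonitrile
  meoh <- C + 4 * H + O             # methanol
  fa <- C + 2 * H + 2 * O           # formic acid
  hac <- 2 * C + 4 * H + 2 * O      # acetic acid
  rule <- function(name, multimer, mass_shift, charge, mode)
    data.frame(name = name, multimer = multimer, mass_shift = mass_shift,
               charge = charge, mode = mode, stringsAsFactors = FALSE)
  rbind(
    rule("[M+H]+",       1,  PROTON_MASS,                         1L, "positive"),
    rule("[M+Na]+",      1,  MONOISOTOPIC[["Na"]] - ELECTRON_MASS, 1L, "positive"),
    rule("[M+K]+",       1,  MONOISOTOPIC[["K"]] - ELECTRON_MASS,  1L, "positive"),
    rule("[M+NH4]+",     1,  N + 4 * H - ELECTRON_MASS,            1L, "positive"),
    rule("[M+2H]2+",     1,  2 * PROTON_MASS,                      2L, "positive"),
    rule("[2M+H]+",      2,  PROTON_MASS,                          1L, "positive"),
    rule("[M+H-H2O]+",   1,  PROTON_MASS - water,                  1L, "positive"),
    rule("[M+ACN+H]+",   1,  acn + PROTON_MASS,                    1L, "positive"),
    rule("[M+CH3OH+H]+", 1,  meoh + PROTON_MASS,                   1L, "positive"),
    rule("[M-H]-",       1,  -PROTON_MASS,                        -1L, "negative"),
    rule("[M+Cl]-",      1,  MONOISOTOPIC[["Cl"]] + ELECTRON_MASS, -1L, "negative"),
    rule("[M+FA-H]-",    1,  fa - PROTON_MASS,                    -1L, "negative"),
    rule("[M-2H]2-",     1,  -2 * PROTON_MASS,                    -2L, "negative"),
    rule("[2M-H]-",      2,  -PROTON_MASS,                        -1L, "negative"),
    rule("[M-H-H2O]-",   1,  -PROTON_MASS - water,                -1L, "negative"),
    rule("[M+Na-2H]-",   1,  MONOISOTOPIC[["Na"]] - 2 * H + ELECTRON_MASS, -1L, "negative"),
    rule("[M+K-2H]-",    1,  MONOISOTOPIC[["K"]] - 2 * H + ELECTRON_MASS,  -1L, "negative"),
    rule("[M+Br]-",      1,  MONOISOTOPIC[["Br"]] + ELECTRON_MASS, -1L, "negative"),
    rule("[M+HAc-H]-",   1,  hac - PROTON_MASS,                   -1L, "negative"))
}

check_adducts <- function(rules) {
  need <- c("name", "multimer", "mass_shift", "charge")
  if (!is.data.frame(rules) || nrow(rules) == 0L ||
      !all(need %in% colnames(rules)))
    stop_input("adduct rules must be a non-empty data frame with columns ",
               paste(need, collapse = ", "))
  if (any(rules$charge == 0)) stop_input("adduct charge must be non-zero")
  if (any(rules$multimer < 1)) stop_input("adduct multimer must be >= 1")
  rules
}

#' Adduct m/z arithmetic
#'
#' `adduct_mz` maps a neutral monoisotopic mass to the observed m/z under
#' each rule; `neutral_candidates` inverts the mapping, enumerating the
#' neutral mass implied by an observed m/z under every rule. The two are
#' exact inverses per rule.
#'
#' @param neutral_mass Positive neutral monoisotopic mass (Da).
#' @param mz Observed m/z.
#' @param rules Adduct rule table (see [default_adducts()]).
#' @return `adduct_mz`: numeric vector of m/z, one per rule.
#'   `neutral_candidates`: data frame `name`, `neutral_mass` (rows with
#'   non-positive implied mass dropped).
#' @export
#' @examples
#' adduct_mz(100, default_adducts()[1, ])  # [M+H]+ -> 101.00728
adduct_mz <- function(neutral_mass, rules = default_adducts()) {
  rules <- check_adducts(rules)
  if (any(neutral_mass <= 0)) stop_input("neutral mass must be positive")
  if (length(neutral_mass) != 1L)
    return(vapply(neutral_mass, adduct_mz, numeric(nrow(rules)), rules = rules))
  setNames((rules$multimer * neutral_mass + rules$mass_shift) /
             abs(rules$charge), rules$name)
}

#' @rdname adduct_mz
#' @export
neutral_candidates <- function(mz, rules = default_adducts()) {
  rules <- check_adducts(rules)
  if (length(mz) != 1L || mz <= 0) stop_input("'mz' must be a single positive value")
  M <- (abs(rules$charge) * mz - rules$mass_shift) / rules$multimer
  keep <- M > 0
  data.frame(name = rules$name[keep], neutral_mass = M[keep],
             stringsAsFactors = FALSE)
}

#' Construct a metabolite-set database
#'
#' @param sets Named list: set name (pathway or taxon) -> character
#'   vector of member compound ids.
#' @param compounds Data frame with columns `compound_id`, `formula` and
#'   optionally `mass` (computed from the formula when absent).
#' @return An object of class `metabolite_set_db`.
#' @export
metabolite_set_db <- function(sets, compounds) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_input("'sets' must be a named list")
  need <- c("compound_id", "formula")
  if (!all(need %in% colnames(compounds)))
    stop_input("'compounds' must have columns compound_id and formula")
  compounds <- compounds[!duplicated(compounds$compound_id), , drop = FALSE]
  if (!"mass" %in% colnames(compounds))
    compounds$mass <- formula_mass(compounds$formula)
  if (any(compounds$mass <= 0)) stop_input("compound masses must be positive")
  unknown <- setdiff(unique(unlist(sets)), compounds$compound_id)
  if (length(unknown))
    stop_input("set member(s) missing from the compound table: ",
               paste(head(unknown, 5), collapse = ", "))
  structure(list(sets = lapply(sets, unique), compounds = compounds),
            class = "metabolite_set_db")
}

#' @export
print.metabolite_set_db <- function(x, ...) {
  cat(sprintf("metabolite_set_db: %d sets over %d compounds\n",
              length(x$sets), nrow(x$compounds)))
  invisible(x)
}

#' Match signature m/z values to database compounds via adducts
#'
#' A compound matches when any of its adduct-predicted m/z values lies
#' within `tolerance_ppm` (relative to the predicted m/z) of any query
#' m/z. Many-to-many matches are retained in the match table; the
#' returned compound set is deduplicated.
#'
#' @param signature_mz Numeric vector of query m/z values.
#' @param db A [metabolite_set_db()].
#' @param rules Adduct rule table.
#' @param tolerance_ppm Matching tolerance in parts per million (>= 0).
#' @return List with `compounds` (character vector of matched compound
#'   ids) and `table` (data frame: `compound_id`, `adduct`,
#'   `predicted_mz`, `query_mz`, `ppm`).
#' @export
match_signature <- function(signature_mz, db, rules = default_adducts(),
                            tolerance_ppm = 5) {
  rules <- check_adducts(rules)
  stopifnot(inherits(db, "metabolite_set_db"))
  if (tolerance_ppm < 0) stop_input("'tolerance_ppm' must be >= 0")
  q <- sort(unique(signature_mz))
  empty <- data.frame(compound_id = character(0), adduct = character(0),
                      predicted_mz = numeric(0), query_mz = numeric(0),
                      ppm = numeric(0), stringsAsFactors = FALSE)
  if (!length(q))
    return(list(compounds = character(0), table = empty))
  cpd <- db$compounds
  hits <- vector("list", nrow(rules))
  for (r in seq_len(nrow(rules))) {
    pred <- (rules$multimer[r] * cpd$mass + rules$mass_shift[r]) /
      abs(rules$charge[r])
    tol <- tolerance_ppm * 1e-6 * pred
    # nearest query m/z to each prediction
    pos <- findInterval(pred, q)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(q))
    dlo <- abs(pred - q[lo]); dhi <- abs(pred - q[hi])
    nearest <- ifelse(dhi < dlo, hi, lo)
    delta <- abs(pred - q[nearest])
    ok <- which(delta <= tol & pred > 0)
    if (length(ok))
      hits[[r]] <- data.frame(compound_id = cpd$compound_id[ok],
                              adduct = rules$name[r],
                              predicted_mz = pred[ok],
                              query_mz = q[nearest[ok]],
                              ppm = delta[ok] / pred[ok] * 1e6,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(hits[!vapply(hits, is.null, logical(1))],
                          list(empty)))
  list(compounds = unique(tab$compound_id), table = tab)
}

#' EASE enrichment score
#'
#' One-sided hypergeometric tail probability of observing at least
#' `k - 1` successes when drawing `n` items from a universe of size `N`
#' containing `m` marked items -- the observed overlap penalised by one,
#' the conservative EASE variant of Fisher's exact test. An overlap of 0
#' (or 1) returns 1.
#'
#' @param k Overlap between the set and the matched signature compounds.
#' @param m Set size (within the matchable universe).
#' @param n Matched signature compound count.
#' @param N Universe size.
#' @return The EASE p-value.
#' @export
ease_test <- function(k, m, n, N) {
  if (length(k) != 1L) return(mapply(ease_test, k, m, n, N))
  if (anyNA(c(k, m, n, N)) || k < 0 || m < 0 || n < 0 || N < 1 ||
      k > min(m, n) || m > N || n > N)
    stop_input("inconsistent counts: need k <= min(m, n) and m, n <= N")
  if (k <= 1) return(1)
  phyper(k - 2, m, N - m, n, lower.tail = FALSE)
}

#' Split a signature by V-score sign
#'
#' Partitions the top-`n_signature` features into the m/z with `V > 0`
#' (relatively increased in cases) and `V < 0` (decreased); features with
#' `V = 0` belong to neither side and are counted separately.
#'
#' @param ranked A `ranked_features` from [rank_by_v()].
#' @param n_signature Signature size (top features by rank).
#' @return List with `v_pos`, `v_neg` (m/z vectors) and `n_zero`.
#' @export
split_by_sign <- function(ranked, n_signature) {
  if (!"V" %in% colnames(ranked)) stop_input("ranking lacks a V column")
  n_signature <- min(check_count(n_signature, "n_signature", min = 0L),
                     nrow(ranked))
  sig <- ranked[ranked$rank <= n_signature, , drop = FALSE]
  list(v_pos = sig$mz[sig$V > 0], v_neg = sig$mz[sig$V < 0],
       n_zero = sum(sig$V == 0))
}

essential_aa <- c("histidine", "isoleucine", "leucine", "lysine",
                  "methionine", "phenylalanine", "threonine", "tryptophan",
                  "valine")

# sets describing biosynthesis of essential amino acids are excluded
# (humans cannot run them); degradation pathways are retained
is_excluded_set <- function(set_names, amino_acids = essential_aa) {
  nm <- tolower(set_names)
  has_aa <- Reduce(`|`, lapply(amino_acids, function(a) grepl(a, nm, fixed = TRUE)))
  has_aa & grepl("synthesis", nm, fixed = TRUE)
}

#' Metabolite-set enrichment of an m/z signature
#'
#' Mummichog-style enrichment: the top `n_signature` features by rank
#' are matched to database compounds via adduct expansion and ppm
#' matching; each set is scored with the EASE hypergeometric tail. The
#' universe is the set of database compounds matchable to the *full*
#' feature list (conditioning on detectability). Sets whose names
#' describe biosynthesis of an essential amino acid are excluded before
#' testing; degradation sets are retained.
#'
#' @param ranked A `ranked_features` computed on the enrichment holdout.
#' @param n_signature Signature size (clipped to the feature count with a
#'   warning if larger).
#' @param db A [metabolite_set_db()].
#' @param rules Adduct rule table.
#' @param tolerance_ppm Matching tolerance (ppm).
#' @param direction `"all"`, `"pos"` (V > 0 features only) or `"neg"`.
#' @param exclude_sets Extra set names to drop, beyond the essential
#'   amino-acid biosynthesis rule.
#' @param alpha Significance threshold on the EASE p (default 0.05,
#'   inclusive).
#' @return An `enrichment_result` data frame: `set`, `k`, `m`, `n`, `N`,
#'   `ease_p`, `significant`, `direction`.
#' @export
run_enrichment <- function(ranked, n_signature, db,
                           rules = default_adducts(), tolerance_ppm = 5,
                           direction = c("all", "pos", "neg"),
                           exclude_sets = character(0), alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(db, "metabolite_set_db"))
  if (n_signature > nrow(ranked)) {
    warning("n_signature exceeds the feature count; clipping")
    n_signature <- nrow(ranked)
  }
  sig <- ranked[ranked$rank <= n_signature, , drop = FALSE]
  if (direction == "pos") sig <- sig[sig$V > 0, , drop = FALSE]
  if (direction == "neg") sig <- sig[sig$V < 0, , drop = FALSE]
  universe_match <- match_signature(ranked$mz, db, rules, tolerance_ppm)
  sig_match <- match_signature(sig$mz, db, rules, tolerance_ppm)
  universe <- universe_match$compounds
  matched <- intersect(sig_match$compounds, universe)
  N <- length(universe); n <- length(matched)
  keep <- !(is_excluded_set(names(db$sets)) | names(db$sets) %in% exclude_sets)
  sets <- db$sets[keep]
  rows <- lapply(names(sets), function(s) {
    members <- intersect(sets[[s]], universe)
    k <- length(intersect(members, matched))
    m <- length(members)
    data.frame(set = s, k = k, m = m, n = n, N = N,
               ease_p = if (N >= 1 && m <= N && n <= N)
                 ease_test(k, m, n, N) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    set = character(0), k = integer(0), m = integer(0), n = integer(0),
    N = integer(0), ease_p = numeric(0)))))
  out$significant <- out$ease_p <= alpha
  out$direction <- direction
  out <- out[order(out$ease_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Build a microbe metabolite-set database from an association table
#'
#' Filters taxon-metabolite associations to those with adjusted
#' `p < alpha` (strict) and positive correlation, drops rows without a
#' compound identifier or formula, and groups the surviving compounds
#' into one metabolite set per taxon (empty sets are dropped). Compound
#' masses are computed from the formulas.
#'
#' @param assoc Data frame with columns `taxon`, `compound_id`,
#'   `formula`, `rho`, `p_adjusted` (e.g. from
#'   [generate_association_table()]).
#' @param alpha Significance threshold (strict; default 0.05).
#' @return A [metabolite_set_db()].
#' @export
build_microbe_db <- function(assoc, alpha = 0.05) {
  need <- c("taxon", "compound_id", "formula", "rho", "p_adjusted")
  if (!all(need %in% colnames(assoc)))
    stop_input("association table lacks column(s): ",
               paste(setdiff(need, colnames(assoc)), collapse = ", "))
  keep <- !is.na(assoc$p_adjusted) & assoc$p_adjusted < alpha &
    !is.na(assoc$rho) & assoc$rho > 0 &
    !is.na(assoc$compound_id) & nzchar(assoc$compound_id) &
    !is.na(assoc$formula) & nzchar(assoc$formula)
  kept <- assoc[keep, , drop = FALSE]
  sets <- split(kept$compound_id, kept$taxon)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0]
  compounds <- kept[!duplicated(kept$compound_id),
                    c("compound_id", "formula"), drop = FALSE]
  if (!length(sets))
    return(structure(list(sets = setNames(list(), character(0)),
                          compounds = data.frame(compound_id = character(0),
                                                 formula = character(0),
                                                 mass = numeric(0))),
                     class = "metabolite_set_db"))
  metabolite_set_db(sets, compounds)
}

#' Read and write metabolite-set databases as GMT-like text
#'
#' `write_gmt` serialises set membership as tab-separated lines (set
#' name, description, member ids) next to a compound CSV (`<path>` with
#' extension `.compounds.csv`) carrying id, formula and mass.
#'
#' @param db A [metabolite_set_db()].
#' @param path Path of the GMT file.
#' @return `write_gmt` invisibly returns `path`; `read_gmt` a
#'   [metabolite_set_db()].
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "metabolite_set_db"))
  lines <- vapply(names(db$sets), function(s)
    paste(c(s, "metabosig set", db$sets[[s]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  write.csv(db$compounds, paste0(path, ".compounds.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  compounds <- read.csv(paste0(path, ".compounds.csv"),
                        stringsAsFactors = FALSE)
  metabolite_set_db(sets, compounds)
}
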