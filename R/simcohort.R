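# Synthetic cohort and peak-table generator -----------------------------

#' Specify a synthetic cohort
#'
#' Defines the statistical structure of a simulated surveillance cohort:
#' subjects with repeated visits, a low-prevalence binary phenotype, a
#' treatment confounder concentrated in cases (an UDCA analogue), sex,
#' technical triplicates, day-of-run batch shifts and intensity-dependent
#' missingness. Defaults emulate the cohort this workflow was designed
#' around: ~8% case prevalence at subject level, 82% of cases treated,
#' roughly balanced sex, one to three visits per subject and technical
#' triplicates.
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject Integer range (vector) from which each
#'   subject's visit count is drawn uniformly.
#' @param case_prevalence Probability a subject is a case (phenotype
#'   positive); class is fixed per subject across visits.
#' @param confounder_rate_in_cases Probability a case subject is treated;
#'   controls are never treated.
#' @param sex_ratio Probability a subject is female.
#' @param n_features Number of m/z features.
#' @param n_planted Number of features carrying a planted class effect.
#' @param planted_log2fc Log2 fold change of planted features in cases;
#'   recycled over planted features, so mixed-sign effects can be planted.
#' @param batch_count Number of day-of-run batches.
#' @param batch_shift_sd SD (log2 scale) of per-batch, per-feature shifts.
#' @param replicate_count Technical replicates per sample (>= 1).
#' @param replicate_noise_sd SD (log2 scale) of replicate noise.
#' @param biological_sd SD (log2 scale) of between-sample biological
#'   variation per feature; sets the effect size `planted_log2fc /
#'   biological_sd` seen by univariate tests.
#' @param missing_rate_base Target marginal missingness; cells go missing
#'   with probability increasing as latent intensity decreases
#'   (low-abundance censoring), calibrated so the marginal rate equals
#'   this value (for rates <= 0.5).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 50, n_features = 100, seed = 1)
#' meta <- generate_cohort(spec)
#' head(meta)
cohort_spec <- function(n_subjects = 348,
                        visits_per_subject = 1:3,
                        case_prevalence = 0.08,
                        confounder_rate_in_cases = 0.82,
                        sex_ratio = 0.5,
                        n_features = 2000,
                        n_planted = 200,
                        planted_log2fc = 1,
                        batch_count = 5,
                        batch_shift_sd = 0.3,
                        replicate_count = 3,
                        replicate_noise_sd = 0.2,
                        biological_sd = 0.8,
                        missing_rate_base = 0.1,
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (!is.numeric(visits_per_subject) || length(visits_per_subject) < 1 ||
      any(visits_per_subject < 1))
    stop_input("'visits_per_subject' must be a range of counts >= 1")
  check_probability(case_prevalence, "case_prevalence")
  check_probability(confounder_rate_in_cases, "confounder_rate_in_cases")
  check_probability(sex_ratio, "sex_ratio")
  check_probability(missing_rate_base, "missing_rate_base")
  n_features <- check_count(n_features, "n_features")
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  if (n_planted > n_features)
    stop_input("'n_planted' must not exceed 'n_features'")
  batch_count <- check_count(batch_count, "batch_count")
  replicate_count <- check_count(replicate_count, "replicate_count")
  if (!is.numeric(planted_log2fc) || length(planted_log2fc) < 1)
    stop_input("'planted_log2fc' must be numeric")
  for (nm in c("batch_shift_sd", "replicate_noise_sd", "biological_sd"))
    if (get(nm) < 0) stop_input(sprintf("'%s' must be >= 0", nm))
  structure(list(
    n_subjects = n_subjects,
    visits_per_subject = as.integer(visits_per_subject),
    case_prevalence = case_prevalence,
    confounder_rate_in_cases = confounder_rate_in_cases,
    sex_ratio = sex_ratio,
    n_features = n_features, n_planted = n_planted,
    planted_log2fc = planted_log2fc,
    batch_count = batch_count, batch_shift_sd = batch_shift_sd,
    replicate_count = replicate_count,
    replicate_noise_sd = replicate_noise_sd,
    biological_sd = biological_sd,
    missing_rate_base = missing_rate_base,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d subjects, prevalence %.2f, %d features (%d planted), seed %d\n",
    x$n_subjects, x$case_prevalence, x$n_features, x$n_planted, x$seed))
  invisible(x)
}

#' Generate cohort metadata
#'
#' Draws subjects, visits, phenotype, sex, treatment, batch and injection
#' order, and expands to one row per (sample, replicate). Class and
#' treatment are assigned at subject level; all replicates of a sample
#' share subject, batch and labels. Sample run order is randomised and
#' day-of-run batches are consecutive blocks of that order.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame (`CohortMetadata`) with columns `sample_id`,
#'   `subject_id`, `replicate_id`, `batch`, `injection_order`,
#'   `class_label`, `sex`, `treatment`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_input("'spec' must be a cohort_spec")
  set.seed(spec$seed)
  ns <- spec$n_subjects
  subj <- sprintf("SUBJ%04d", seq_len(ns))
  visits <- sample(spec$visits_per_subject, ns, replace = TRUE)
  class_label <- rbinom(ns, 1L, spec$case_prevalence)
  sex <- ifelse(rbinom(ns, 1L, spec$sex_ratio) == 1L, "F", "M")
  treatment <- ifelse(class_label == 1L,
                      rbinom(ns, 1L, spec$confounder_rate_in_cases), 0L)
  samples <- data.frame(
    subject_id = rep(subj, visits),
    visit = unlist(lapply(visits, seq_len)),
    stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_V%d", samples$subject_id, samples$visit)
  nsamp <- nrow(samples)
  run_order <- sample.int(nsamp)           # randomised injection order
  samples$injection_order <- run_order
  block <- ceiling(nsamp / spec$batch_count)
  samples$batch <- sprintf("B%02d", ceiling(run_order / block))
  idx <- match(samples$subject_id, subj)
  samples$class_label <- class_label[idx]
  samples$sex <- sex[idx]
  samples$treatment <- treatment[idx]
  out <- samples[rep(seq_len(nsamp), each = spec$replicate_count), ]
  out$replicate_id <- sprintf("R%d", rep(seq_len(spec$replicate_count), nsamp))
  rownames(out) <- NULL
  out[, c("sample_id", "subject_id", "replicate_id", "batch",
          "injection_order", "class_label", "sex", "treatment")]
}

# m/z grid: uniform in [70, 1000] Da with a 2 ppm minimum spacing,
# mirroring ppm binning of high-resolution DI-MS peak tables.
draw_mz_grid <- function(n, fixed_mz = NULL, lo = 70, hi = 1000,
                         min_ppm = 2) {
  if (anyDuplicated(fixed_mz)) stop_input("fixed m/z values must be unique")
  mz <- sort(c(fixed_mz, runif(n - length(fixed_mz), lo, hi)))
  repeat {
    fixed_at <- match(fixed_mz, mz)
    viol <- which(diff(mz) < min_ppm * 1e-6 * mz[-length(mz)])
    if (!length(viol)) break
    # move the random member of each too-close pair, never a fixed mass
    move <- ifelse((viol + 1L) %in% fixed_at, viol, viol + 1L)
    move <- setdiff(move, fixed_at)
    if (!length(move))
      stop_input("fixed m/z values violate the 2 ppm spacing")
    mz[move] <- runif(length(move), lo, hi)
    mz <- sort(mz)
  }
  mz
}

#' Generate a replicate-level peak table
#'
#' Simulates log-normal baseline intensities per feature, a planted
#' multiplicative class effect on a chosen subset of features, additive
#' per-batch log-scale shifts, replicate-level log-normal noise, and
#' intensity-dependent missingness (low-abundance censoring) whose
#' marginal rate equals `spec$missing_rate_base`.
#'
#' @param meta Metadata from [generate_cohort()].
#' @param spec The same [cohort_spec()].
#' @param planted_mz Optional numeric vector of exact m/z values at which
#'   to place planted features (e.g. adduct masses of a taxon's
#'   compounds, so that downstream enrichment has a recoverable truth).
#'   Its length must not exceed `spec$n_planted`.
#' @param anchor_mz Optional numeric vector of exact m/z values placed in
#'   the feature grid *without* a planted effect (e.g. adduct masses of
#'   all database compounds, so the enrichment universe contains
#'   non-differential matchable features).
#' @return A list with elements `peaks` (a [peak_table()]), `planted`
#'   (integer indices of planted features) and `planted_log2fc` (the
#'   per-planted-feature effect, recycled from the spec).
#' @export
generate_peak_table <- function(meta, spec, planted_mz = NULL,
                                anchor_mz = NULL) {
  if (!inherits(spec, "cohort_spec")) stop_input("'spec' must be a cohort_spec")
  if (!is.null(planted_mz) && length(planted_mz) > spec$n_planted)
    stop_input("length(planted_mz) must not exceed spec$n_planted")
  anchor_mz <- setdiff(anchor_mz, planted_mz)
  fixed <- c(planted_mz, anchor_mz)
  if (length(fixed) > spec$n_features)
    stop_input("more fixed m/z values than features")
  set.seed(spec$seed + 1L)
  p <- spec$n_features
  mz <- draw_mz_grid(p, fixed_mz = fixed)
  planted <- if (!is.null(planted_mz)) {
    c(match(planted_mz, mz),
      sample(setdiff(seq_len(p), match(planted_mz, mz)),
             spec$n_planted - length(planted_mz)))
  } else if (spec$n_planted > 0) {
    sort(sample.int(p, spec$n_planted))
  } else integer(0)
  lfc <- rep_len(spec$planted_log2fc, length(planted))

  usamp <- unique(meta$sample_id)
  smeta <- meta[!duplicated(meta$sample_id), ]
  nsamp <- length(usamp)
  base <- rnorm(p, mean = 17, sd = 1.5)        # log2 baseline abundance
  beta <- numeric(p); beta[planted] <- lfc
  batches <- sort(unique(meta$batch))
  shift <- matrix(rnorm(length(batches) * p, 0, spec$batch_shift_sd),
                  nrow = length(batches),
                  dimnames = list(batches, NULL))
  # sample-level latent log2 intensity
  L <- matrix(rnorm(nsamp * p, 0, spec$biological_sd), nsamp, p)
  L <- L + rep(base, each = nsamp)
  L <- L + outer(smeta$class_label, beta)
  L <- L + shift[smeta$batch, , drop = FALSE]

  rep_rows <- match(meta$sample_id, usamp)
  R <- L[rep_rows, , drop = FALSE] +
    matrix(rnorm(nrow(meta) * p, 0, spec$replicate_noise_sd),
           nrow(meta), p)
  # low-abundance censoring: P(missing) = min(1, 2 * base_rate * (1 - u)),
  # u the pooled intensity rank scaled to (0, 1); marginal rate = base_rate.
  if (spec$missing_rate_base > 0) {
    u <- (rank(R, ties.method = "first") - 0.5) / length(R)
    pmiss <- pmin(1, 2 * spec$missing_rate_base * (1 - u))
    R[runif(length(R)) < pmiss] <- NA
  }
  pt <- peak_table(2^R, sample_id = meta$sample_id,
                   replicate_id = meta$replicate_id, mz = mz)
  list(peaks = pt, planted = planted, planted_log2fc = lfc)
}

#' Generate a synthetic microbe-metabolite association table
#'
#' Emulates the input of a gut-microbiome metabolite-set atlas: rows of
#' (taxon, compound, formula, correlation, adjusted p). A controllable
#' fraction of rows passes the downstream inclusion filter
#' (`p_adjusted < 0.05` and `rho > 0`), so database-builder recovery is
#' testable. Formulas are drawn from [builtin_formulas()].
#'
#' @param n_taxa Number of taxa.
#' @param n_compounds Number of distinct compounds in the pool.
#' @param frac_significant Probability any row passes the filter.
#' @param seed Integer seed.
#' @param compounds_per_taxon Range of compounds per taxon (drawn
#'   uniformly, capped at `n_compounds`).
#' @return A data frame with columns `taxon`, `compound_id`, `formula`,
#'   `rho`, `p_adjusted`.
#' @export
generate_association_table <- function(n_taxa, n_compounds,
                                       frac_significant = 0.5, seed = 1L,
                                       compounds_per_taxon = 5:15) {
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_compounds <- check_count(n_compounds, "n_compounds")
  check_probability(frac_significant, "frac_significant")
  set.seed(as.integer(seed))
  pool <- builtin_formulas()
  cpd <- data.frame(
    compound_id = sprintf("CPD%05d", seq_len(n_compounds)),
    formula = unname(pool[((seq_len(n_compounds) - 1L) %% length(pool)) + 1L]),
    stringsAsFactors = FALSE)
  sizes <- pmin(sample(compounds_per_taxon, n_taxa, replace = TRUE),
                n_compounds)
  rows <- do.call(rbind, lapply(seq_len(n_taxa), function(i) {
    members <- sample.int(n_compounds, sizes[i])
    data.frame(taxon = sprintf("Taxon_%03d", i),
               compound_id = cpd$compound_id[members],
               formula = cpd$formula[members],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  sig <- runif(n) < frac_significant
  rho <- numeric(n); padj <- numeric(n)
  rho[sig] <- runif(sum(sig), 0.1, 0.9)
  padj[sig] <- runif(sum(sig), 1e-4, 0.0499)
  # non-significant rows fail the filter either by sign or by p-value
  neg <- !sig & runif(n) < 0.5
  rho[neg] <- runif(sum(neg), -0.9, -0.1)
  padj[neg] <- runif(sum(neg))
  rest <- !sig & !neg
  rho[rest] <- runif(sum(rest), 0.1, 0.9)
  padj[rest] <- runif(sum(rest), 0.05, 1)
  rows$rho <- rho
  rows$p_adjusted <- padj
  rows
}
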