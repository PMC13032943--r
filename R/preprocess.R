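# Peak-table preprocessing ----------------------------------------------

#' Filter features by sample-level missingness
#'
#' A feature counts as present in a sample if at least one of the sample's
#' technical replicates recorded a signal. Features whose fraction of
#' missing samples is strictly greater than `max_missing_fraction` are
#' removed (so a feature missing in exactly 20% of samples is retained at
#' the default threshold).
#'
#' @param table A [peak_table()].
#' @param max_missing_fraction Maximum tolerated fraction of samples with
#'   no signal (default 0.20).
#' @return The filtered [peak_table()], with a data-frame attribute
#'   `"removed"` reporting the dropped features and their missing
#'   fractions (also exposed via `attr(x, "removed")`).
#' @export
filter_missing <- function(table, max_missing_fraction = 0.20) {
  stopifnot(inherits(table, "peak_table"))
  check_probability(max_missing_fraction, "max_missing_fraction")
  if (nrow(table$intensities) == 0L || ncol(table$intensities) == 0L)
    stop_input("peak table is empty")
  grp <- factor(table$sample_id, levels = unique(table$sample_id))
  present <- rowsum((!is.na(table$intensities)) + 0, grp) > 0
  frac_missing <- colMeans(!present)
  drop <- frac_missing > max_missing_fraction
  out <- peak_table(table$intensities[, !drop, drop = FALSE],
                    table$sample_id, table$replicate_id,
                    table$mz[!drop], table$mode)
  attr(out, "removed") <- data.frame(mz = table$mz[drop],
                                     frac_missing = frac_missing[drop],
                                     row.names = NULL)
  out
}

#' Quantile-normalise intensities across samples
#'
#' Replaces each sample's sorted non-missing values by the across-sample
#' means of order statistics, so that complete samples share one value
#' distribution. Ties receive the mean of their tied quantile values.
#' Delegates to `limma::normalizeQuantiles` (samples as columns).
#'
#' @param x Numeric matrix, rows = samples (or replicate measurements),
#'   columns = features; `NA` permitted.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_input("need at least one sample")
  if (nrow(x) == 1L) return(x)
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Autoscale features
#'
#' Centres every feature to mean zero and scales to unit sample standard
#' deviation (denominator n - 1). Constant features are set to all zeros
#' and flagged in the `"constant_features"` attribute rather than failing.
#'
#' @param x Numeric matrix, rows = observations, columns = features.
#' @return Scaled matrix with attribute `constant_features` (logical).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2, sd, na.rm = TRUE)
  constant <- !is.finite(sdev) | sdev == 0
  sdev[constant] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  out[, constant] <- ifelse(is.na(out[, constant]), NA, 0)
  attr(out, "constant_features") <- constant
  out
}

#' Centre out per-batch location shifts
#'
#' Per feature and per batch, subtracts the batch median and adds back the
#' per-feature global median, removing day-of-run location shifts while
#' preserving each feature's overall level.
#'
#' @param x Numeric matrix, rows = observations, columns = features.
#' @param batch Batch label per row.
#' @return Matrix of the same shape.
#' @export
batch_center <- function(x, batch) {
  x <- as.matrix(x)
  if (length(batch) != nrow(x))
    stop_input("'batch' must have one label per row of 'x'")
  if (anyNA(batch)) stop_input("unknown (missing) batch label")
  batch <- as.character(batch)
  global_med <- apply(x, 2, median, na.rm = TRUE)
  for (b in unique(batch)) {
    rows <- batch == b
    bmed <- apply(x[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, bmed - global_med, "-")
  }
  x
}

#' Average technical replicates to sample level
#'
#' Per sample and feature, takes the arithmetic mean over replicates with
#' non-missing values; a cell whose replicates are all missing stays
#' missing.
#'
#' @param x Numeric matrix at replicate level (rows = replicate
#'   measurements) or a [peak_table()].
#' @param sample_id Sample identifier per row (taken from the peak table
#'   when `x` is one).
#' @return Matrix with one row per sample (rownames = sample ids).
#' @export
average_replicates <- function(x, sample_id = NULL) {
  if (inherits(x, "peak_table")) {
    sample_id <- x$sample_id
    x <- x$intensities
  }
  x <- as.matrix(x)
  if (is.null(sample_id) || length(sample_id) != nrow(x))
    stop_input("'sample_id' must have one entry per row")
  grp <- factor(sample_id, levels = unique(sample_id))
  sums <- rowsum(ifelse(is.na(x), 0, x), grp)
  cnts <- rowsum((!is.na(x)) + 0, grp)
  out <- sums / cnts
  out[cnts == 0] <- NA
  rownames(out) <- levels(grp)
  out
}

#' Impute remaining missing values by the half-minimum rule
#'
#' Missing cells are replaced by half the feature's minimum observed
#' value, the usual metabolomics floor convention for values censored at
#' the detection limit. Features with no observed value at all are left
#' missing.
#'
#' @param x Numeric matrix.
#' @return Matrix with the same shape.
#' @export
impute_halfmin <- function(x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss) && !all(miss))
      x[miss, j] <- min(x[, j], na.rm = TRUE) / 2
  }
  x
}

#' Run the default preprocessing pipeline
#'
#' Applies, in order: missingness filtering, quantile normalisation (at
#' replicate level), half-minimum imputation, autoscaling, per-batch
#' median centering, and replicate averaging. Two sample-level matrices
#' are returned: `scaled` (autoscaled + batch-centred; the input for
#' statistical tests and classifiers) and `intensity`
#' (quantile-normalised, imputed, unscaled; the input for fold-change
#' computation, where log ratios remain defined). The applied steps are
#' recorded in order in `provenance`.
#'
#' @param table A [peak_table()].
#' @param meta Metadata from [generate_cohort()] (or any data frame with
#'   `sample_id`, `replicate_id`, `batch`); used for batch labels.
#' @param max_missing Missingness threshold for [filter_missing()].
#' @param batch_correct Apply [batch_center()]? Default `TRUE`.
#' @return A list of class `normalized_matrix` with elements `scaled`,
#'   `intensity`, `mz`, `sample_id`, `provenance`, `constant_features`,
#'   `removed`.
#' @export
preprocess_peaks <- function(table, meta, max_missing = 0.20,
                             batch_correct = TRUE) {
  stopifnot(inherits(table, "peak_table"))
  key_t <- paste(table$sample_id, table$replicate_id)
  key_m <- paste(meta$sample_id, meta$replicate_id)
  if (!all(key_t %in% key_m))
    stop_input("peak-table replicate without a metadata row")
  meta <- meta[match(key_t, key_m), ]
  provenance <- character(0)

  filt <- filter_missing(table, max_missing)
  provenance <- c(provenance, "filter_missing")
  qn <- quantile_normalize(filt$intensities)
  provenance <- c(provenance, "quantile_normalize")
  imp <- impute_halfmin(qn)
  provenance <- c(provenance, "impute_halfmin")
  sc <- autoscale(imp)
  constant <- attr(sc, "constant_features")
  provenance <- c(provenance, "autoscale")
  if (batch_correct) {
    sc <- batch_center(sc, meta$batch)
    provenance <- c(provenance, "batch_center")
  }
  scaled <- average_replicates(sc, filt$sample_id)
  intensity <- average_replicates(imp, filt$sample_id)
  provenance <- c(provenance, "average_replicates")
  structure(list(scaled = scaled, intensity = intensity, mz = filt$mz,
                 sample_id = rownames(scaled), provenance = provenance,
                 constant_features = constant,
                 removed = attr(filt, "removed")),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d samples x %d features\n",
              nrow(x$scaled), ncol(x$scaled)))
  cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}
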