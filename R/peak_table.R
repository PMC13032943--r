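# peak_table: replicate-level intensity container -----------------------

#' Construct a peak table
#'
#' A `peak_table` holds replicate-level intensities: one row per technical
#' replicate measurement, one column per m/z feature. Missing measurements
#' are `NA`; present intensities must be non-negative.
#'
#' @param intensities Numeric matrix (rows = replicate measurements,
#'   columns = features). `NA` marks a missing signal.
#' @param sample_id Character vector, one entry per row.
#' @param replicate_id Vector (coerced to character), one entry per row.
#' @param mz Numeric vector of feature m/z values in Da; strictly positive
#'   and unique within a mode.
#' @param mode Ionisation mode tag, `"positive"` or `"negative"`. Carried
#'   for format fidelity; no mode-specific logic is applied.
#'
#' @return An object of class `peak_table`: a list with elements
#'   `intensities`, `sample_id`, `replicate_id`, `mz`, `mode`.
#' @export
peak_table <- function(intensities, sample_id, replicate_id, mz,
                       mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(sample_id) ||
      nrow(intensities) != length(replicate_id))
    stop_input("sample_id/replicate_id length must equal nrow(intensities)")
  if (ncol(intensities) != length(mz))
    stop_input("length(mz) must equal ncol(intensities)")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop_input("m/z values must be strictly positive and finite")
  if (anyDuplicated(mz))
    stop_input("m/z values must be unique within a mode")
  if (any(intensities < 0, na.rm = TRUE))
    stop_input("intensities must be non-negative where present")
  key <- paste(sample_id, replicate_id, sep = "::")
  if (anyDuplicated(key))
    stop_input("(sample_id, replicate_id) pairs must be unique")
  colnames(intensities) <- format_mz(mz)
  rownames(intensities) <- key
  structure(
    list(intensities = intensities,
         sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         mz = as.numeric(mz), mode = mode),
    class = "peak_table")
}

format_mz <- function(mz) sprintf("%.6f", mz)

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf(
    "peak_table: %d replicate measurements (%d samples) x %d m/z features [%s mode]\n",
    nrow(x$intensities), length(unique(x$sample_id)), length(x$mz), x$mode))
  cat(sprintf("  m/z range: %.4f - %.4f Da; missing cells: %.1f%%\n",
              min(x$mz), max(x$mz),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Read and write peak tables
#'
#' The on-disk dialect is a TSV whose first two columns are `sample_id` and
#' `replicate_id`; the remaining column headers are the m/z values printed
#' with six decimals. Missing cells are `NA`.
#'
#' @param x A [peak_table()].
#' @param path File path.
#' @param mode Ionisation mode tag to attach on read.
#' @return `write_peak_table` invisibly returns `path`; `read_peak_table`
#'   returns a [peak_table()].
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  df <- data.frame(sample_id = x$sample_id, replicate_id = x$replicate_id,
                   x$intensities, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path, mode = "positive") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mzcols <- setdiff(colnames(df), c("sample_id", "replicate_id"))
  peak_table(as.matrix(df[, mzcols, drop = FALSE]),
             sample_id = df$sample_id, replicate_id = df$replicate_id,
             mz = as.numeric(mzcols), mode = mode)
}
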