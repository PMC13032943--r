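# Univariate feature ranking --------------------------------------------

#' Combined V-score
#'
#' `V = -log10(p) * log2(fold_change)`: the product of the evidence
#' against the null (t-test p-value) and the direction/magnitude of
#' change (log2 fold change). `V` is antisymmetric in fold-change
#' inversion and zero at fold change 1. A p-value of exactly zero is
#' clipped to the smallest positive double (with a warning); non-positive
#' fold changes are an error since log2 is undefined there.
#'
#' @param p_value Numeric p-values in \[0, 1\].
#' @param fold_change Positive fold changes (case mean / control mean).
#' @return Numeric V-scores.
#' @export
#' @examples
#' vscore(0.01, 4)     #  4
#' vscore(0.001, 0.25) # -6
vscore <- function(p_value, fold_change) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop_input("fold changes must be strictly positive")
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop_input("p-values must be in [0, 1]")
  clip <- !is.na(p_value) & p_value == 0
  if (any(clip)) {
    warning("p-value of 0 clipped to smallest positive representable double")
    p_value[clip] <- .Machine$double.xmin
  }
  -log10(p_value) * log2(fold_change)
}

# vectorised Welch two-sample t-test, NA-aware; returns p (and t, df)
welch_columns <- function(x, pos) {
  count <- function(m) colSums(!is.na(m))
  x1 <- x[pos, , drop = FALSE]; x0 <- x[!pos, , drop = FALSE]
  n1 <- count(x1); n0 <- count(x0)
  m1 <- colMeans(x1, na.rm = TRUE); m0 <- colMeans(x0, na.rm = TRUE)
  v1 <- apply(x1, 2, var, na.rm = TRUE)
  v0 <- apply(x0, 2, var, na.rm = TRUE)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tt), df)
  degenerate <- !is.finite(p)
  p[degenerate] <- 1
  list(p = p, t = tt, df = df, degenerate = degenerate)
}

rank_order <- function(criterion, p, mz) {
  ord <- order(-criterion, p, mz)
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)
  rk
}

#' Rank features by absolute V-score
#'
#' Per feature: a Welch two-sample t-test on the test-scale matrix
#' (typically autoscaled), a fold change (case mean over control mean) on
#' the intensity-scale matrix where log ratios are defined, the combined
#' [vscore()], and a 1-based rank by descending `|V|` (ties broken by
#' smaller p-value, then lower m/z). Features with zero variance in both
#' classes get p = 1, V = 0 and a flag.
#'
#' @param x_fc Sample-by-feature matrix of positive intensities used for
#'   fold change (e.g. `preprocess_peaks()$intensity`).
#' @param x_test Sample-by-feature matrix used for the t-test (e.g.
#'   `preprocess_peaks()$scaled`); same features and samples as `x_fc`.
#' @param labels Binary class label per row.
#' @param mz Feature m/z values; parsed from `colnames(x_fc)` if omitted.
#' @param positive Optional positive-class value.
#' @return A `ranked_features` data frame: `mz`, `p_value`,
#'   `fold_change`, `V`, `criterion` (`|V|`), `rank`, `flagged`, with
#'   attribute `rank_by = "abs_V"`.
#' @export
rank_by_v <- function(x_fc, x_test, labels, mz = NULL, positive = NULL) {
  x_fc <- as.matrix(x_fc); x_test <- as.matrix(x_test)
  if (!all(dim(x_fc) == dim(x_test)))
    stop_input("'x_fc' and 'x_test' must have identical shape")
  if (is.null(mz)) mz <- as.numeric(colnames(x_fc))
  if (anyNA(mz)) stop_input("provide numeric 'mz' (colnames not parseable)")
  f <- as_binary_factor(labels, positive)
  pos <- f == positive_level(f)
  if (!any(pos) || all(pos)) stop_input("both classes must be present")
  if (any(x_fc <= 0, na.rm = TRUE))
    stop_input("'x_fc' must be strictly positive (use imputed intensities)")
  w <- welch_columns(x_test, pos)
  fc <- colMeans(x_fc[pos, , drop = FALSE], na.rm = TRUE) /
        colMeans(x_fc[!pos, , drop = FALSE], na.rm = TRUE)
  V <- vscore(w$p, fc)
  V[w$degenerate] <- 0
  out <- data.frame(mz = mz, p_value = w$p, fold_change = fc, V = V,
                    criterion = abs(V),
                    rank = rank_order(abs(V), w$p, mz),
                    flagged = w$degenerate, row.names = NULL)
  attr(out, "rank_by") <- "abs_V"
  class(out) <- c("ranked_features", "data.frame")
  out
}

# logistic regression of y on one predictor with a tiny ridge penalty on
# the slope; used when the ML fit separates perfectly
ridge_logistic_z <- function(xj, y, lambda = 1e-6, iter = 50L) {
  X <- cbind(1, xj)
  beta <- c(0, 0)
  P <- diag(c(0, lambda))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w) + P
    score <- crossprod(X, y - mu) - P %*% beta
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- drop(plogis(X %*% beta))
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))) + P)))
  beta[2] / se[2]
}

#' Rank features by absolute logistic Wald z
#'
#' Fits, per feature, a single-predictor logistic regression of class on
#' the feature (plus intercept) by maximum likelihood, extracts the Wald
#' statistic `z = coefficient / standard error`, and ranks by descending
#' `|z|`. Perfectly separating features are refit with a tiny ridge
#' penalty (1e-6) to stabilise `|z|` and flagged.
#'
#' @param x Sample-by-feature matrix (typically the scaled matrix).
#' @param labels Binary class label per row.
#' @param mz Feature m/z values; parsed from `colnames(x)` if omitted.
#' @param positive Optional positive-class value.
#' @return A `ranked_features` data frame: `mz`, `wald_z`, `criterion`
#'   (`|z|`), `rank`, `flagged` (separation), attribute
#'   `rank_by = "abs_Z"`.
#' @export
rank_by_logistic <- function(x, labels, mz = NULL, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(mz)) mz <- as.numeric(colnames(x))
  if (anyNA(mz)) stop_input("provide numeric 'mz' (colnames not parseable)")
  f <- as_binary_factor(labels, positive)
  y <- as.numeric(f == positive_level(f))
  if (all(y == 0) || all(y == 1)) stop_input("both classes must be present")
  p <- ncol(x)
  z <- numeric(p); flagged <- logical(p)
  for (j in seq_len(p)) {
    xj <- x[, j]
    if (sd(xj) == 0) { z[j] <- 0; flagged[j] <- TRUE; next }
    sep <- FALSE
    fit <- withCallingHandlers(
      suppressWarnings(glm.fit(cbind(1, xj), y,
                               family = stats::binomial())),
      warning = function(w) invokeRestart("muffleWarning"))
    # Wald z from the unpenalised fit
    eta <- drop(cbind(1, xj) %*% fit$coefficients)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    sep <- !fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10) ||
      fit$boundary
    if (sep || any(!is.finite(fit$coefficients))) {
      z[j] <- ridge_logistic_z(xj, y)
      flagged[j] <- TRUE
    } else {
      info <- crossprod(cbind(1, xj), cbind(1, xj) * w)
      se <- sqrt(diag(solve(info)))
      z[j] <- fit$coefficients[2] / se[2]
    }
    if (!is.finite(z[j])) { z[j] <- 0; flagged[j] <- TRUE }
  }
  out <- data.frame(mz = mz, wald_z = z, criterion = abs(z),
                    rank = rank_order(abs(z), rep(1, p), mz),
                    flagged = flagged, row.names = NULL)
  attr(out, "rank_by") <- "abs_Z"
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Spearman agreement between two ranking criteria
#'
#' Tie-corrected Spearman correlation between two per-feature criterion
#' vectors (e.g. `|V|` for two different phenotypes), with the
#' large-sample approximation for the p-value. Used to check whether two
#' phenotypes induce confounded rankings.
#'
#' @param criterion_a,criterion_b Numeric vectors over the same feature
#'   universe.
#' @return A list of class `rank_agreement`: `rho`, `p_value`.
#' @export
spearman_rank_agreement <- function(criterion_a, criterion_b) {
  if (length(criterion_a) != length(criterion_b))
    stop_input("criterion vectors must have equal length")
  if (sd(criterion_a) == 0 || sd(criterion_b) == 0)
    stop_input("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(criterion_a, criterion_b,
                                  method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value),
            class = "rank_agreement")
}

#' @export
print.rank_agreement <- function(x, ...) {
  cat(sprintf("rank_agreement: rho = %.3f, p = %.3g\n", x$rho, x$p_value))
  invisible(x)
}

#' Per-fold feature rankings on training samples
#'
#' Computes a [rank_by_v()] (or [rank_by_logistic()]) ranking within each
#' cross-validation fold using only that fold's *training* samples, as
#' consumed by the signature-determination step.
#'
#' @param x_fc,x_test Sample-level matrices as in [rank_by_v()] (for
#'   `method = "logistic"` only `x_test` is used).
#' @param labels Binary class label per row.
#' @param folds Integer fold id per row.
#' @param method `"v"` or `"logistic"`.
#' @param mz Feature m/z values.
#' @param positive Optional positive-class value.
#' @return Named list (one element per fold id) of `ranked_features`.
#' @export
per_fold_rankings <- function(x_fc, x_test, labels, folds, method = c("v", "logistic"),
                              mz = NULL, positive = NULL) {
  method <- match.arg(method)
  res <- lapply(sort(unique(folds)), function(fk) {
    train <- folds != fk
    if (method == "v") {
      rank_by_v(x_fc[train, , drop = FALSE], x_test[train, , drop = FALSE],
                labels[train], mz = mz, positive = positive)
    } else {
      rank_by_logistic(x_test[train, , drop = FALSE], labels[train],
                       mz = mz, positive = positive)
    }
  })
  names(res) <- as.character(sort(unique(folds)))
  res
}
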