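# Signature-size determination by stepwise permutation ------------------

# permute (in a copy) the columns listed in 'features' across all rows
permute_features <- function(x, features) {
  for (j in features) x[, j] <- x[sample.int(nrow(x)), j]
  x
}

#' Permute the top-k ranked features and re-evaluate
#'
#' Within each fold, independently permutes the abundances of that fold's
#' top-k ranked features across samples (destroying their association
#' with the label), retrains the fold's forest and scores its held-out
#' samples; returns the AUROC of the scores pooled over folds. The input
#' matrix is never mutated.
#'
#' @param x Sample-by-feature matrix.
#' @param labels Binary class label per row.
#' @param folds Integer fold id per row.
#' @param rankings Per-fold rankings from [per_fold_rankings()] (or a
#'   single `ranked_features` recycled over folds).
#' @param k Number of top-ranked features to permute (0 = baseline);
#'   values above the feature count are clipped with a warning.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (permutations and forests).
#' @param positive Optional positive-class value.
#' @return Pooled AUROC (numeric scalar).
#' @export
permute_topk_and_eval <- function(x, labels, folds, rankings, k,
                                  n_trees = 500, seed = 1L,
                                  positive = NULL) {
  x <- as.matrix(x)
  if (k > ncol(x)) {
    warning("k exceeds the feature count; clipping")
    k <- ncol(x)
  }
  fold_ids <- sort(unique(folds))
  if (inherits(rankings, "ranked_features"))
    rankings <- setNames(rep(list(rankings), length(fold_ids)),
                         as.character(fold_ids))
  f <- as_binary_factor(labels, positive)
  pos_lvl <- positive_level(f)
  mtry <- floor(sqrt(ncol(x)))
  ids <- rownames(x); if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  pooled <- vector("list", length(fold_ids))
  for (i in seq_along(fold_ids)) {
    fk <- fold_ids[i]
    rk <- rankings[[as.character(fk)]]
    top <- order(rk$rank)[seq_len(k)]
    set.seed(as.integer(seed) + 131 * i + k)
    xi <- if (k > 0) permute_features(x, top) else x
    train <- folds != fk
    fit <- ranger::ranger(x = xi[train, , drop = FALSE], y = f[train],
                          num.trees = n_trees, mtry = mtry,
                          probability = TRUE, num.threads = 1L,
                          seed = as.integer(seed) + i)
    pr <- predict(fit, data = xi[!train, , drop = FALSE],
                  num.threads = 1L)$predictions[, pos_lvl]
    pooled[[i]] <- data.frame(score = pr, label = f[!train])
  }
  sc <- do.call(rbind, pooled)
  auroc(sc$score, sc$label, positive = pos_lvl)
}

#' Build permutation elimination curves
#'
#' Evaluates pooled AUROC on a common grid of permuted-feature counts
#' (`0, step, 2*step, ...`) for three arms: `ranked` (each fold's top-k
#' features permuted), `random` (an accumulating random feature set of
#' the same size permuted) and `label_shuffled` (ranked permutation with
#' subject-level permuted class labels, the second negative control).
#' Stops early when the ranked arm has been within `stop_tol` of the
#' label-shuffled arm for `stop_after` consecutive grid points.
#'
#' @inheritParams permute_topk_and_eval
#' @param subjects Subject id per row (for the label-shuffled arm).
#' @param step Grid spacing (default 50).
#' @param max_k Largest permuted count (default: all features).
#' @param stop_tol AUROC difference treated as "within noise" (0.05).
#' @param stop_after Consecutive within-noise points that trigger the
#'   early stop (3).
#' @return An `elimination_curve` data frame: `k`, `auroc_ranked`,
#'   `auroc_random`, `auroc_shuffled`; attributes `step`, `seed`.
#' @export
build_elimination_curves <- function(x, labels, folds, rankings, subjects,
                                     step = 50, n_trees = 500, seed = 1L,
                                     max_k = NULL, stop_tol = 0.05,
                                     stop_after = 3L, positive = NULL) {
  x <- as.matrix(x)
  step <- check_count(step, "step")
  p <- ncol(x)
  if (is.null(max_k)) max_k <- p
  grid <- unique(pmin(seq(0, max_k, by = step), p))
  # labels are permuted within folds so every fold keeps its class
  # balance and the control arm sits at chance rather than below it
  shuffled_labels <- permute_labels_by_subject(labels, subjects,
                                               seed = as.integer(seed) + 7L,
                                               within = folds)
  fold_ids <- sort(unique(folds))
  if (inherits(rankings, "ranked_features"))
    rankings <- setNames(rep(list(rankings), length(fold_ids)),
                         as.character(fold_ids))
  # accumulating random feature order, one per fold, drawn once
  set.seed(as.integer(seed) + 17L)
  random_orders <- lapply(fold_ids, function(i) sample.int(p))
  names(random_orders) <- as.character(fold_ids)
  random_rankings <- lapply(random_orders, function(ord) {
    rk <- integer(p); rk[ord] <- seq_len(p)
    structure(data.frame(rank = rk), class = c("ranked_features", "data.frame"))
  })
  res <- data.frame(k = integer(0), auroc_ranked = numeric(0),
                    auroc_random = numeric(0), auroc_shuffled = numeric(0))
  within_noise <- 0L
  for (k in grid) {
    a_ranked <- permute_topk_and_eval(x, labels, folds, rankings, k,
                                      n_trees, seed, positive)
    a_random <- if (k == 0) a_ranked else
      permute_topk_and_eval(x, labels, folds, random_rankings, k,
                            n_trees, seed, positive)
    a_shuffled <- permute_topk_and_eval(x, shuffled_labels, folds, rankings,
                                        k, n_trees, seed, positive)
    res <- rbind(res, data.frame(k = k, auroc_ranked = a_ranked,
                                 auroc_random = a_random,
                                 auroc_shuffled = a_shuffled))
    within_noise <- if (abs(a_ranked - a_shuffled) <= stop_tol)
      within_noise + 1L else 0L
    # never stop before the elbow detector's minimum of 5 grid points
    if (within_noise >= stop_after && nrow(res) >= 5L && k < max(grid)) break
  }
  attr(res, "step") <- step
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("elimination_curve", "data.frame")
  res
}

#' Locate the signature size at the flattest point of the curve
#'
#' Smooths the ranked-arm AUROC-versus-k series with a local-linear
#' regression (loess, tricube weights; `span <= 0` or too few points for
#' the span disables smoothing), takes forward-difference derivatives on
#' the grid, and returns the smallest interior grid point whose absolute
#' derivative is within `flat_tol` of the flattest observed derivative
#' (near-flat points are treated as tied; ties resolve toward smaller
#' k). A curve with no material decline (`< min_decline` AUROC) raises
#' the no-signal flag and reports size 0. The result is invariant to
#' affine rescaling of the AUROC axis.
#'
#' @param curve An `elimination_curve` (or data frame with `k` and
#'   `auroc_ranked`).
#' @param span Loess span (default 0.75, the usual plotting-smoother
#'   default).
#' @param flat_tol Fraction of the derivative-magnitude range within
#'   which derivatives count as tied with the flattest (default 0.05).
#' @param min_decline Minimum AUROC decline for the curve to count as
#'   carrying signal (default 0.02).
#' @return An object of class `signature_threshold`: `n_signature`,
#'   `no_signal`, `curve`, `smoothed`, `derivative_at_threshold`,
#'   `span`.
#' @export
elbow_threshold <- function(curve, span = 0.75, flat_tol = 0.05,
                            min_decline = 0.02) {
  k <- curve$k; y <- curve$auroc_ranked
  if (length(k) < 5L) stop_input("need at least 5 grid points")
  if (is.unsorted(k, strictly = TRUE)) stop_input("grid must be strictly increasing")
  ys <- if (span > 0 && floor(span * length(k)) >= 4L) {
    fit <- loess(y ~ k, span = span, degree = 1,
                 control = loess.control(surface = "direct"))
    predict(fit, newdata = data.frame(k = k))
  } else y
  d <- diff(ys) / diff(k)            # derivative attached to left grid point
  interior <- seq_along(d) >= 2L     # k past the first grid step
  ad <- abs(d[interior])
  kk <- k[which(interior)]
  no_signal <- (max(ys) - min(ys)) < min_decline
  if (no_signal) {
    n_sig <- 0L
  } else {
    tied <- ad <= min(ad) + flat_tol * (max(ad) - min(ad))
    n_sig <- min(kk[tied])
  }
  structure(list(n_signature = n_sig, no_signal = no_signal,
                 curve = curve, smoothed = ys,
                 derivative_at_threshold =
                   if (no_signal) NA_real_ else d[match(n_sig, k)],
                 span = span),
            class = "signature_threshold")
}

#' @export
print.signature_threshold <- function(x, ...) {
  if (x$no_signal) {
    cat("signature_threshold: no decline detected (no-signal flag)\n")
  } else {
    cat(sprintf("signature_threshold: %d top-ranked features (|d AUROC/dk| = %.2g at threshold)\n",
                x$n_signature, abs(x$derivative_at_threshold)))
  }
  invisible(x)
}
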