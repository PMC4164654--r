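#' Confusion counts and classification metrics
#'
#' `confusion_counts()` builds a validated TP/TN/FP/FN record;
#' `compute_metrics()` derives the four performance measures used
#' throughout the pipeline:
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP),}
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Sensitivity is the fraction of positive (sumoylation) samples recovered,
#' specificity the fraction of negative (acetylation) samples recovered.
#' Accuracy alone is misleading on imbalanced classes — predicting the
#' majority class on a 218/926 dataset already scores 80.94% — so the
#' Matthews correlation coefficient, which balances both error types, is
#' the headline measure. `MCC` is defined as 0 when its denominator is 0;
#' `SN` (`SP`) is an error when there are no positives (negatives) to
#' evaluate.
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @param cc A `confusion_counts` object (or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`).
#' @return `confusion_counts()`: a classed list of the four counts.
#'   `compute_metrics()`: a list with elements `sensitivity`,
#'   `specificity`, `accuracy` (in \[0, 1\]) and `mcc` (in \[-1, 1\]).
#' @export
#' @examples
#' compute_metrics(confusion_counts(TP = 0, TN = 926, FP = 0, FN = 218))
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @export
compute_metrics <- function(cc) {
  TP <- as.numeric(cc$TP); TN <- as.numeric(cc$TN)
  FP <- as.numeric(cc$FP); FN <- as.numeric(cc$FN)
  total <- TP + TN + FP + FN
  if (total == 0) stop("all confusion counts are zero")
  if (TP + FN == 0) stop("no positive samples: sensitivity undefined")
  if (TN + FP == 0) stop("no negative samples: specificity undefined")
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       accuracy = (TP + TN) / total,
       mcc = if (denom == 0) 0 else (TP * TN - FP * FN) / denom)
}

#' Random-forest classifier specification
#'
#' The classifier follows the Weka 3.6.4 random-forest defaults: 10 trees,
#' unlimited depth, and `floor(log2(m)) + 1` candidate features per split
#' for `m` features. Prediction is the majority vote of the trees.
#'
#' @param n_trees Number of trees in the ensemble.
#' @param mtry Candidate features per split; `NULL` applies the
#'   `floor(log2(m)) + 1` rule at fit time.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(n_trees = 10L, mtry = NULL) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry),
            class = "classifier_spec")
}

resolve_mtry <- function(spec, m) {
  if (!is.null(spec$mtry)) min(spec$mtry, m) else
    min(floor(log2(m)) + 1L, m)
}

#' Train a random-forest classifier
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Two-level class labels, one per row.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed controlling tree randomness; the same
#'   (data, spec, seed) triple always yields the same predictor.
#' @return A fitted `randomForest` object; predict with
#'   [predict_classifier()].
#' @export
train_classifier <- function(features, labels, spec = classifier_spec(),
                             seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("training data contain a single class")
  withr::with_seed(seed,
    randomForest::randomForest(
      x = features, y = y,
      ntree = spec$n_trees,
      mtry = resolve_mtry(spec, ncol(features))))
}

#' Predict classes for new samples
#'
#' @param model A predictor from [train_classifier()].
#' @param features Numeric matrix with the same columns as at training.
#' @return Character vector of predicted class labels (majority vote).
#' @export
predict_classifier <- function(model, features) {
  as.character(stats::predict(model, features))
}

# Deterministic per-fold seeds derived from the master seed.
fold_seeds <- function(seed, n_folds) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_folds))
}

#' Jackknife (leave-one-out) evaluation of the classifier
#'
#' Strict jackknife cross-validation: each sample is predicted by a model
#' trained on the remaining n - 1 samples; the confusion counts aggregate
#' all n held-out predictions. Each fold's classifier uses a seed derived
#' deterministically from `seed` and the fold index, so results are exactly
#' reproducible.
#'
#' @inheritParams train_classifier
#' @param positive Label value counted as the positive class; defaults to
#'   `"positive"` if present among the labels, otherwise the rarer level.
#' @return A `confusion_counts` object.
#' @export
jackknife_evaluate <- function(features, labels, spec = classifier_spec(),
                               seed = 1L, positive = NULL) {
  evaluate_classifier(features, labels, spec = spec, seed = seed,
                      folds = NULL, positive = positive)
}

#' Cross-validated confusion counts
#'
#' Generalization of [jackknife_evaluate()]: with `folds = NULL` it is the
#' strict leave-one-out jackknife; with an integer `folds` it performs
#' stratified k-fold cross-validation (each sample still predicted exactly
#' once). The k-fold mode exists because leave-one-out across a whole
#' incremental-feature-selection grid costs one model fit per sample per
#' prefix, which is far beyond a desk-scale run.
#'
#' @inheritParams jackknife_evaluate
#' @param folds `NULL` for leave-one-out, or number of stratified folds.
#' @return A `confusion_counts` object.
#' @export
evaluate_classifier <- function(features, labels, spec = classifier_spec(),
                                seed = 1L, folds = NULL, positive = NULL) {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  stopifnot(length(labels) == n, n >= 2L)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("need exactly two classes, got ", length(lev))
  if (is.null(positive)) {
    positive <- if ("positive" %in% lev) "positive" else
      lev[which.min(tabulate(match(labels, lev)))]
  }

  if (is.null(folds)) {
    assignment <- seq_len(n)            # one fold per sample
    n_folds <- n
  } else {
    stopifnot(folds >= 2L, folds <= n)
    n_folds <- as.integer(folds)
    assignment <- integer(n)
    # stratified: spread each class across folds under the master seed
    assignment <- withr::with_seed(seed, {
      a <- integer(n)
      for (cl in lev) {
        idx <- which(labels == cl)
        a[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      a
    })
  }

  seeds <- fold_seeds(seed, n_folds)
  predicted <- character(n)
  for (f in seq_len(n_folds)) {
    test_idx <- which(assignment == f)
    if (!length(test_idx)) next
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(labels[train_idx])) < 2L) {
      stop("training fold ", f, " contains a single class")
    }
    # the whole fold runs under its derived seed: majority-vote ties at
    # prediction time draw from the RNG, so they must be seeded too
    predicted[test_idx] <- withr::with_seed(seeds[f], {
      model <- train_classifier(features[train_idx, , drop = FALSE],
                                labels[train_idx], spec = spec,
                                seed = seeds[f])
      predict_classifier(model, features[test_idx, , drop = FALSE])
    })
  }

  is_pos <- labels == positive
  pred_pos <- predicted == positive
  confusion_counts(TP = sum(is_pos & pred_pos),
                   TN = sum(!is_pos & !pred_pos),
                   FP = sum(!is_pos & pred_pos),
                   FN = sum(is_pos & !pred_pos))
}

#' Incremental feature selection over an mRMR ranking
#'
#' For a grid of prefix sizes k, evaluates a random-forest classifier on
#' the top-k features of the ranking by cross-validation and records the
#' confusion counts and SN/SP/ACC/MCC per k. The optimal k is the smallest
#' k attaining the maximal MCC; the corresponding top-k descriptors form
#' the optimal feature set. Prefix sizes whose classifier cannot be built
#' are recorded with missing metrics rather than aborting the run.
#'
#' @param ranking An `mrmr_ranking` from [mrmr_rank()].
#' @param features The feature matrix the ranking was computed on.
#' @param labels Class labels per row (default: `"labels"` attribute).
#' @param k_min,k_max,k_step Prefix-size grid; `k_max` defaults to all
#'   ranked features and is always included in the grid.
#' @param spec A [classifier_spec()].
#' @param seed Master seed for fold assignment and per-fold classifiers.
#' @param folds `NULL` for strict jackknife (leave-one-out), or a number of
#'   stratified folds; see [evaluate_classifier()].
#' @return An object of class `ifs_result` with components `curve` (data
#'   frame: k, TP, TN, FP, FN, sensitivity, specificity, accuracy, mcc),
#'   `optimal_k`, `optimal_mcc`, `optimal_features` (top-k rows of the
#'   ranking) and `call` metadata. Methods: `print`, `summary`, `plot`.
#' @export
ifs_fit <- function(ranking, features, labels = attr(features, "labels"),
                    k_min = 1L, k_max = nrow(ranking), k_step = 1L,
                    spec = classifier_spec(), seed = 1L, folds = NULL) {
  stopifnot(inherits(ranking, "mrmr_ranking"), nrow(ranking) >= 1L,
            k_max <= nrow(ranking), k_min >= 1L, k_min <= k_max)
  if (is.null(labels)) stop("labels are required")
  ks <- unique(c(seq(k_min, k_max, by = k_step), k_max))

  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    cols <- ranking$index[seq_len(k)]
    cc <- tryCatch(
      evaluate_classifier(features[, cols, drop = FALSE], labels,
                          spec = spec, seed = seed, folds = folds),
      error = function(e) NULL)
    if (is.null(cc)) {
      rows[[i]] <- data.frame(k = k, TP = NA, TN = NA, FP = NA, FN = NA,
                              sensitivity = NA, specificity = NA,
                              accuracy = NA, mcc = NA)
    } else {
      m <- compute_metrics(cc)
      rows[[i]] <- data.frame(k = k, TP = cc$TP, TN = cc$TN, FP = cc$FP,
                              FN = cc$FN, sensitivity = m$sensitivity,
                              specificity = m$specificity,
                              accuracy = m$accuracy, mcc = m$mcc)
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  if (all(is.na(curve$mcc))) stop("no prefix size produced a classifier")
  best <- which(curve$mcc == max(curve$mcc, na.rm = TRUE))[1L]
  optimal_k <- curve$k[best]

  structure(list(
    curve = curve,
    optimal_k = optimal_k,
    optimal_mcc = curve$mcc[best],
    optimal_features = as.data.frame(ranking)[seq_len(optimal_k), ,
                                              drop = FALSE],
    n_samples = nrow(features),
    cv = if (is.null(folds)) "jackknife (leave-one-out)" else
      paste0("stratified ", folds, "-fold"),
    spec = spec, seed = seed), class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("Incremental feature selection (", x$cv, ", ",
      x$spec$n_trees, "-tree random forest)\n", sep = "")
  cat(sprintf("  %d samples, %d prefix sizes evaluated\n",
              x$n_samples, nrow(x$curve)))
  cat(sprintf("  optimal k = %d with MCC = %.4f\n",
              x$optimal_k, x$optimal_mcc))
  invisible(x)
}

#' @export
summary.ifs_result <- function(object, ...) {
  best <- object$curve[object$curve$k == object$optimal_k, ]
  cat("IFS curve over k =", paste(range(object$curve$k), collapse = ".."),
      "(", nrow(object$curve), "evaluations )\n")
  cat(sprintf(
    "Optimal classifier: k = %d, SN = %.4f, SP = %.4f, ACC = %.4f, MCC = %.4f\n",
    object$optimal_k, best$sensitivity, best$specificity, best$accuracy,
    best$mcc))
  cat("Optimal feature set by block:\n")
  if ("block" %in% names(object$optimal_features)) {
    print(table(object$optimal_features$block))
  }
  invisible(object)
}

#' Plot an IFS curve
#'
#' MCC of the cross-validated classifier against the number of top-ranked
#' features used, with the optimal prefix size marked.
#'
#' @param x An `ifs_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ifs_result <- function(x, ...) {
  ok <- !is.na(x$curve$mcc)
  graphics::plot(x$curve$k[ok], x$curve$mcc[ok], type = "l",
                 xlab = "number of top mRMR features (k)", ylab = "MCC",
                 main = "IFS curve", ...)
  graphics::abline(v = x$optimal_k, lty = 2)
  graphics::points(x$optimal_k, x$optimal_mcc, pch = 19)
  invisible(x)
}

#' Write an IFS curve as TSV
#'
#' @param result An `ifs_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ifs <- function(result, path) {
  utils::write.table(result$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
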