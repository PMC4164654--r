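#' Run the full discrimination workflow over split datasets
#'
#' Convenience driver reproducing the study design end to end: encode all
#' windows once, split the negatives into `n_parts` balanced parts, and for
#' each resulting dataset (all positives + one negative part) compute the
#' mRMR ranking and fit the incremental feature selection; finally combine
#' the per-dataset optimal feature sets (duplicates removed).
#'
#' @param windows A `peptide_windows` data frame with both classes.
#' @param providers A [provider_bundle()] covering the windows' proteins.
#' @param n_parts Number of negative parts / datasets.
#' @param seed Master seed (negative split, fold assignment, classifiers).
#' @param spec A [classifier_spec()].
#' @param folds `NULL` for strict jackknife, or a stratified fold count;
#'   see [evaluate_classifier()].
#' @param k_max,k_step Prefix-size grid of the IFS stage (default: all 646
#'   features in steps of `k_step`).
#' @return A list of class `ptm_pipeline` with components `datasets` (per
#'   dataset: `name`, `ranking`, `ifs`), `combined` (a
#'   [combine_optimal_sets()] result) and `features` (the encoded matrix).
#' @export
ptm_pipeline <- function(windows, providers, n_parts = 3L, seed = 1L,
                         spec = classifier_spec(), folds = NULL,
                         k_max = NULL, k_step = 1L) {
  features <- encode_windows(windows, providers)
  desc <- attr(features, "descriptors")
  labels <- attr(features, "labels")
  parts <- split_negatives(windows, n_parts = n_parts, seed = seed)
  df <- as.data.frame(windows)
  row_key <- paste(df$protein_id, df$center_pos)

  datasets <- lapply(parts, function(part) {
    pw <- as.data.frame(partition_windows(part))
    idx <- match(paste(pw$protein_id, pw$center_pos), row_key)
    x <- features[idx, , drop = FALSE]
    attr(x, "descriptors") <- desc
    y <- labels[idx]
    ranking <- mrmr_rank(x, labels = y, descriptors = desc)
    fit <- ifs_fit(ranking, x, labels = y,
                   k_max = if (is.null(k_max)) nrow(ranking) else k_max,
                   k_step = k_step, spec = spec, seed = seed, folds = folds)
    list(name = part$name, ranking = ranking, ifs = fit)
  })

  combined <- combine_optimal_sets(
    lapply(datasets, function(d) d$ifs$optimal_features),
    set_names = vapply(datasets, `[[`, character(1), "name"))

  structure(list(datasets = datasets, combined = combined,
                 features = features),
            class = "ptm_pipeline")
}

#' @export
print.ptm_pipeline <- function(x, ...) {
  cat("Sumoylation/acetylation discrimination pipeline:",
      length(x$datasets), "datasets\n")
  for (d in x$datasets) {
    best <- d$ifs
    cat(sprintf("  %s: optimal k = %d, MCC = %.4f\n", d$name,
                best$optimal_k, best$optimal_mcc))
  }
  cat("Combined optimal feature set:", nrow(x$combined), "features\n")
  invisible(x)
}
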