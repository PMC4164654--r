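#' Discretize a continuous feature into three levels
#'
#' The mutual-information estimates behind the mRMR criterion require
#' categorical variables. Continuous features are cut at mean +/- one
#' standard deviation into codes -1 (low), 0 (middle) and +1 (high); for a
#' normally distributed feature the middle bin holds about 68% of the
#' values. Features with at most two distinct values (binary and one-hot
#' columns, constants) are returned unchanged — their native states are
#' already categorical.
#'
#' @param values Numeric vector.
#' @return For binary/constant input, `values` unchanged; otherwise an
#'   integer vector of codes in \{-1, 0, 1\}.
#' @export
#' @examples
#' discretize(c(0, 0, 1, 1))       # binary: unchanged
#' discretize(rnorm(10))           # three-level codes
discretize <- function(values) {
  stopifnot(is.numeric(values))
  if (length(unique(values)) <= 2L) {
    return(values)
  }
  mu <- mean(values)
  s <- stats::sd(values)
  codes <- integer(length(values))
  codes[values < mu - s] <- -1L
  codes[values > mu + s] <- 1L
  codes
}

#' Plug-in mutual information of two categorical variables
#'
#' \deqn{I(X;Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}}
#' with the convention \eqn{0 \log 0 = 0}. Probabilities are empirical
#' (plug-in) estimates from the paired observations. The result is in bits;
#' the base only scales the value and never changes an mRMR ranking.
#'
#' @param x,y Vectors of equal positive length; treated as categorical.
#' @return Non-negative mutual information in bits.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
mutual_information <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty input")
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  tab <- table(x, y)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# Integer-code a discretized feature matrix for the fast MI engine:
# every column is mapped to codes 1..n_states (at most 3 states each).
code_features <- function(features) {
  n <- nrow(features)
  m <- ncol(features)
  coded <- matrix(1L, n, m)
  for (j in seq_len(m)) {
    d <- discretize(features[, j])
    coded[, j] <- match(d, sort(unique(d)))
  }
  coded
}

# MI (bits) of every column of a coded matrix against one coded vector.
# `ind` is the precomputed list of per-state column indicator matrices and
# `margins` the per-state column counts; both over the same coded matrix.
mi_columns_vs_vector <- function(ind, margins, s, n) {
  m <- ncol(ind[[1]])
  mi <- numeric(m)
  for (b in sort(unique(s))) {
    idx <- which(s == b)
    nb <- length(idx)
    for (a in seq_along(ind)) {
      cab <- colSums(ind[[a]][idx, , drop = FALSE])
      ma <- margins[[a]]
      pos <- cab > 0
      mi[pos] <- mi[pos] +
        (cab[pos] / n) * log2((cab[pos] * n) / (ma[pos] * nb))
    }
  }
  mi
}

#' Rank features by the mRMR difference criterion
#'
#' Greedy maximum-relevance minimum-redundancy ranking in the difference
#' form: the first feature maximizes relevance (mutual information with the
#' class label); each subsequent feature maximizes
#' \deqn{A - B = I(f;\,class) - \frac{1}{|S|}\sum_{s \in S} I(f;\,s)}
#' where \eqn{S} is the set already selected. The higher `A - B`, the
#' higher the rank. Continuous features are discretized with [discretize()]
#' (three levels at mean +/- sd); binary/one-hot columns keep their native
#' states. Ties are broken toward the smaller column index, making the
#' ranking fully deterministic.
#'
#' @param features Numeric matrix, one row per sample, one column per
#'   feature (e.g. from [encode_windows()]).
#' @param labels Class labels, one per row; any two-level vector. Defaults
#'   to the `"labels"` attribute of `features` if present.
#' @param descriptors Optional data frame describing the columns (as from
#'   [feature_descriptors()]); defaults to the `"descriptors"` attribute.
#' @return An object of class `mrmr_ranking`: a data frame with one row per
#'   feature in rank order and columns `rank`, `index` (original column),
#'   `block`/`site`/`subtype` (if descriptors are available), `relevance`,
#'   `redundancy` (mean MI against the features selected before it, 0 for
#'   rank 1) and `score` (`relevance - redundancy` at selection time).
#' @export
mrmr_rank <- function(features, labels = attr(features, "labels"),
                      descriptors = attr(features, "descriptors")) {
  stopifnot(is.matrix(features), ncol(features) >= 2L)
  if (is.null(labels)) stop("labels are required")
  labels <- as.integer(factor(labels))
  stopifnot(length(labels) == nrow(features))

  n <- nrow(features)
  m <- ncol(features)
  coded <- code_features(features)
  n_states <- max(coded)
  ind <- lapply(seq_len(n_states), function(a) coded == a)
  margins <- lapply(ind, colSums)

  relevance <- mi_columns_vs_vector(ind, margins, labels, n)

  rank_order <- integer(m)
  red_at_pick <- numeric(m)
  score_at_pick <- numeric(m)
  red_sum <- numeric(m)
  remaining <- rep(TRUE, m)
  for (k in seq_len(m)) {
    if (k == 1L) {
      score <- relevance
      red <- numeric(m)
    } else {
      red <- red_sum / (k - 1)
      score <- relevance - red
    }
    score[!remaining] <- -Inf
    pick <- which.max(score)  # ties -> smallest index
    rank_order[k] <- pick
    red_at_pick[k] <- red[pick]
    score_at_pick[k] <- if (k == 1L) relevance[pick] else score[pick]
    remaining[pick] <- FALSE
    if (k < m) {
      red_sum <- red_sum + mi_columns_vs_vector(ind, margins, coded[, pick], n)
    }
  }

  out <- data.frame(rank = seq_len(m), index = rank_order,
                    stringsAsFactors = FALSE)
  if (!is.null(descriptors)) {
    out <- cbind(out, descriptors[rank_order, c("block", "site", "subtype"),
                                  drop = FALSE])
  } else if (!is.null(colnames(features))) {
    out$feature <- colnames(features)[rank_order]
  }
  out$relevance <- relevance[rank_order]
  out$redundancy <- red_at_pick
  out$score <- score_at_pick
  rownames(out) <- NULL
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' @export
print.mrmr_ranking <- function(x, n = 10L, ...) {
  cat("mRMR ranking (difference criterion) of", nrow(x), "features\n")
  cat("Top", min(n, nrow(x)), "features:\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Write an mRMR ranking as TSV
#'
#' @param ranking An `mrmr_ranking` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrmr <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
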