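#' Combine optimal feature sets across datasets
#'
#' When the negative class is split into parts, each resulting dataset
#' yields its own optimal feature set; the combined set is their union with
#' duplicates removed. Descriptors are identified by their (block, site,
#' subtype) triple, so sets originating from different mRMR tables combine
#' correctly regardless of rank or index.
#'
#' @param sets A list of descriptor data frames (each with columns `block`,
#'   `site`, `subtype`; e.g. the `optimal_features` of an [ifs_fit()]
#'   result).
#' @param set_names Names for provenance tracking; defaults to
#'   `names(sets)` or `"set1"`, `"set2"`, ...
#' @return A data frame of class `combined_optimal_set` with columns
#'   `block`, `site`, `subtype` and `provenance` (comma-separated names of
#'   the sets that selected the descriptor).
#' @export
combine_optimal_sets <- function(sets, set_names = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(set_names)) {
    set_names <- if (!is.null(names(sets))) names(sets) else
      paste0("set", seq_along(sets))
  }
  stopifnot(length(set_names) == length(sets))
  pieces <- lapply(seq_along(sets), function(i) {
    d <- as.data.frame(sets[[i]])[, c("block", "site", "subtype"),
                                  drop = FALSE]
    d$provenance <- rep(set_names[i], nrow(d))
    d
  })
  all_rows <- do.call(rbind, pieces)
  if (nrow(all_rows) == 0L) {
    out <- data.frame(block = character(), site = integer(),
                      subtype = character(), provenance = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("combined_optimal_set", "data.frame")
    return(out)
  }
  key <- paste(all_rows$block, all_rows$site, all_rows$subtype, sep = "\r")
  prov <- vapply(split(all_rows$provenance, key), function(p)
    paste(unique(p), collapse = ","), character(1))
  first <- !duplicated(key)
  out <- all_rows[first, c("block", "site", "subtype"), drop = FALSE]
  out$provenance <- unname(prov[key[first]])
  rownames(out) <- NULL
  class(out) <- c("combined_optimal_set", "data.frame")
  out
}

block_levels <- function() {
  c("PSSM", "AAFactor", "SecondaryStructure", "SolventAccessibility",
    "Disorder")
}

block_totals <- function() {
  c(PSSM = 420L, AAFactor = 100L, SecondaryStructure = 63L,
    SolventAccessibility = 42L, Disorder = 21L)
}

#' Distribution of an optimal feature set over the five feature blocks
#'
#' @param set A descriptor data frame (columns `block`, `site`, `subtype`),
#'   e.g. a [combine_optimal_sets()] result.
#' @return A data frame with one row per block: `block`, `count`,
#'   `block_total` (number of features the block contributes to the full
#'   encoding) and `fraction_of_block` (`count / block_total`).
#' @export
block_distribution <- function(set) {
  d <- as.data.frame(set)
  counts <- table(factor(d$block, levels = block_levels()))
  totals <- block_totals()
  data.frame(block = block_levels(),
             count = as.integer(counts),
             block_total = as.integer(totals[block_levels()]),
             fraction_of_block = as.numeric(counts / totals[block_levels()]),
             stringsAsFactors = FALSE)
}

#' Distribution of an optimal feature set over window sites
#'
#' Cross-tabulates the descriptors by window site (1..21) and block. The
#' per-block margins equal [block_distribution()] counts; the per-site
#' margins sum to the set size.
#'
#' @inheritParams block_distribution
#' @return An integer matrix with 21 rows (sites) and one column per block.
#' @export
site_distribution <- function(set) {
  d <- as.data.frame(set)
  tab <- table(factor(d$site, levels = 1:21),
               factor(d$block, levels = block_levels()))
  m <- matrix(as.integer(tab), nrow = 21,
              dimnames = list(site = 1:21, block = block_levels()))
  m
}

#' Distribution of an optimal feature set over the subtypes of one block
#'
#' Subtypes are the within-slot identities: the 20 amino acids for `PSSM`,
#' the five Atchley factors for `AAFactor`, helix/strand/other for
#' `SecondaryStructure`, buried/exposed for `SolventAccessibility`, and
#' `score` for `Disorder`.
#'
#' @inheritParams block_distribution
#' @param block One of the five block names.
#' @return Named integer vector of counts over the block's full subtype
#'   space (zeros included).
#' @export
subtype_distribution <- function(set, block) {
  block <- match.arg(block, block_levels())
  desc <- feature_descriptors()
  levels <- unique(desc$subtype[desc$block == block])
  d <- as.data.frame(set)
  d <- d[d$block == block, , drop = FALSE]
  counts <- table(factor(d$subtype, levels = levels))
  stats::setNames(as.integer(counts), levels)
}

#' Positional amino-acid frequency matrix of one window class
#'
#' For every window site, the relative frequency of each of the 20 amino
#' acids among the windows of the requested class. BLANK slots are excluded
#' from both numerator and denominator, so every row with at least one
#' counted residue sums to 1. This is the matrix a sequence-logo tool
#' renders; site 11 is always 100% lysine.
#'
#' @param windows A `peptide_windows` data frame.
#' @param class `"positive"` (sumoylation) or `"negative"` (acetylation).
#' @return A 21 x 20 numeric matrix (rows = sites, columns =
#'   [amino_acids()]); rows where every window is BLANK are `NaN`.
#' @export
position_frequency_matrix <- function(windows,
                                      class = c("positive", "negative")) {
  class <- match.arg(class)
  df <- as.data.frame(windows)
  df <- df[df$label == class, , drop = FALSE]
  if (!nrow(df)) stop("no windows of class '", class, "'")
  slots <- window_slots(df)
  aa <- amino_acids()
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 20L,
                dimnames = list(site = 1:21, aa))
  for (s in seq_len(WINDOW_SIZE)) {
    letters_s <- slots[, s]
    letters_s <- letters_s[!is.na(letters_s)]
    counts <- table(factor(letters_s, levels = aa))
    out[s, ] <- as.numeric(counts) / length(letters_s)
  }
  out
}
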