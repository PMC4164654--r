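#' Canonical descriptor table for the 646-feature encoding
#'
#' Every feature of the window encoding is identified by a (block, site,
#' subtype) triple. The assembled vector concatenates five blocks in fixed
#' order, each block slot-major (site 1 first):
#'
#' | block                  | subtypes per site                       | count |
#' |------------------------|-----------------------------------------|-------|
#' | `PSSM`                 | 20 amino acids, alphabetical            | 420   |
#' | `AAFactor`             | 5 Atchley factors (center site skipped) | 100   |
#' | `SecondaryStructure`   | helix, strand, other                    | 63    |
#' | `SolventAccessibility` | buried, exposed                         | 42    |
#' | `Disorder`             | score                                   | 21    |
#'
#' The central lysine (site 11) is invariant, so its amino-acid factor
#' values carry no information and the `AAFactor` block covers only the 20
#' surrounding sites.
#'
#' @return A data frame with 646 rows and columns `index` (1..646), `block`,
#'   `site` (1..21) and `subtype`.
#' @export
#' @examples
#' table(feature_descriptors()$block)
feature_descriptors <- function() {
  aa <- amino_acids()
  factors <- colnames(atchley_factors())
  blocks <- list(
    PSSM = expand.grid(subtype = aa, site = 1:21,
                       stringsAsFactors = FALSE)[, 2:1],
    AAFactor = expand.grid(subtype = factors, site = setdiff(1:21, 11),
                           stringsAsFactors = FALSE)[, 2:1],
    SecondaryStructure = expand.grid(subtype = c("helix", "strand", "other"),
                                     site = 1:21,
                                     stringsAsFactors = FALSE)[, 2:1],
    SolventAccessibility = expand.grid(subtype = c("buried", "exposed"),
                                       site = 1:21,
                                       stringsAsFactors = FALSE)[, 2:1],
    Disorder = data.frame(site = 1:21, subtype = "score",
                          stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(blocks), function(b) {
    d <- blocks[[b]]
    data.frame(block = b, site = as.integer(d$site), subtype = d$subtype,
               stringsAsFactors = FALSE)
  }))
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

feature_names <- function(desc = feature_descriptors()) {
  abbrev <- c(PSSM = "PSSM", AAFactor = "AAF", SecondaryStructure = "SS",
              SolventAccessibility = "SA", Disorder = "DIS")
  sprintf("%s_s%02d_%s", abbrev[desc$block], desc$site, desc$subtype)
}

# Sequence positions covered by the window of one table row; NA for BLANK.
window_positions <- function(center_pos) {
  center_pos + (seq_len(WINDOW_SIZE) - CENTER_SITE)
}

check_provider_row <- function(providers, protein_id, pos, len_needed) {
  if (!protein_id %in% names(providers$pssm)) {
    stop("no provider tables for protein '", protein_id, "'")
  }
  len <- nrow(providers$pssm[[protein_id]])
  if (len_needed > len) {
    stop("provider tables for protein '", protein_id, "' cover ", len,
         " residues but position ", len_needed, " is required")
  }
}

#' Encode one peptide window with a single feature block
#'
#' These are the five block encoders behind [encode_windows()], exposed for
#' inspection and testing. Each takes one row of a `peptide_windows` table
#' plus the provider bundle and returns the block's feature values in
#' canonical order. BLANK slots contribute zeros in every block.
#'
#' * `encode_pssm()`: the provider's 20 conservation scores per slot,
#'   slot-major, columns ordered as [amino_acids()] (420 values).
#' * `encode_aafactors()`: the five Atchley factor values of each of the 20
#'   surrounding residues, in the order polarity, secondary_structure,
#'   molecular_volume, codon_diversity, electrostatic_charge (100 values).
#'   The invariant central lysine is skipped.
#' * `encode_secondary_structure()`: per slot, one-hot (helix, strand,
#'   other); `H` -> (1,0,0), `E` -> (0,1,0), `O` -> (0,0,1) (63 values).
#' * `encode_solvent_accessibility()`: per slot, one-hot (buried, exposed);
#'   `B` -> (1,0), `X` -> (0,1) (42 values).
#' * `encode_disorder()`: the provider's disorder score per slot (21
#'   values).
#'
#' @param window A single-row `peptide_windows` data frame (or a list with
#'   `protein_id`, `center_pos` and `s1`..`s21` entries).
#' @param providers A [provider_bundle()].
#' @param factor_table A 20 x 5 matrix of amino-acid factor values; defaults
#'   to the embedded [atchley_factors()] table.
#' @return A numeric vector (length 420/100/63/42/21 by encoder).
#' @name block-encoders
#' @export
encode_pssm <- function(window, providers) {
  w <- as_window_row(window)
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 20L)
  pos <- window_positions(w$center_pos)
  filled <- which(!is.na(w$slots))
  if (length(filled)) {
    check_provider_row(providers, w$protein_id, pos, max(pos[filled]))
    m <- providers$pssm[[w$protein_id]]
    out[filled, ] <- m[pos[filled], , drop = FALSE]
  }
  as.vector(t(out))
}

#' @rdname block-encoders
#' @export
encode_aafactors <- function(window, factor_table = atchley_factors()) {
  w <- as_window_row(window)
  sites <- setdiff(seq_len(WINDOW_SIZE), CENTER_SITE)
  out <- matrix(0, nrow = length(sites), ncol = 5L)
  for (i in seq_along(sites)) {
    letter <- w$slots[sites[i]]
    if (is.na(letter)) next
    if (!letter %in% rownames(factor_table)) {
      stop("no amino-acid factor values for letter '", letter, "'")
    }
    out[i, ] <- factor_table[letter, ]
  }
  as.vector(t(out))
}

#' @rdname block-encoders
#' @export
encode_secondary_structure <- function(window, providers) {
  w <- as_window_row(window)
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 3L)
  pos <- window_positions(w$center_pos)
  filled <- which(!is.na(w$slots))
  if (length(filled)) {
    check_provider_row(providers, w$protein_id, pos, max(pos[filled]))
    states <- strsplit(providers$ss[[w$protein_id]], "")[[1]][pos[filled]]
    code <- match(states, c("H", "E", "O"))
    if (anyNA(code)) {
      stop("unknown secondary-structure state for protein '",
           w$protein_id, "': ", paste(states[is.na(code)], collapse = ", "))
    }
    out[cbind(filled, code)] <- 1
  }
  as.vector(t(out))
}

#' @rdname block-encoders
#' @export
encode_solvent_accessibility <- function(window, providers) {
  w <- as_window_row(window)
  out <- matrix(0, nrow = WINDOW_SIZE, ncol = 2L)
  pos <- window_positions(w$center_pos)
  filled <- which(!is.na(w$slots))
  if (length(filled)) {
    check_provider_row(providers, w$protein_id, pos, max(pos[filled]))
    states <- strsplit(providers$sa[[w$protein_id]], "")[[1]][pos[filled]]
    code <- match(states, c("B", "X"))
    if (anyNA(code)) {
      stop("unknown solvent-accessibility state for protein '",
           w$protein_id, "': ", paste(states[is.na(code)], collapse = ", "))
    }
    out[cbind(filled, code)] <- 1
  }
  as.vector(t(out))
}

#' @rdname block-encoders
#' @export
encode_disorder <- function(window, providers) {
  w <- as_window_row(window)
  out <- numeric(WINDOW_SIZE)
  pos <- window_positions(w$center_pos)
  filled <- which(!is.na(w$slots))
  if (length(filled)) {
    check_provider_row(providers, w$protein_id, pos, max(pos[filled]))
    out[filled] <- providers$disorder[[w$protein_id]][pos[filled]]
  }
  out
}

as_window_row <- function(window) {
  df <- as.data.frame(window, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 1L)
  slots <- as.character(unlist(df[paste0("s", seq_len(WINDOW_SIZE))]))
  list(protein_id = df$protein_id[1],
       center_pos = as.integer(df$center_pos[1]),
       slots = slots)
}

#' Assemble the full 646-feature vector for one window
#'
#' Concatenates the five block encodings in the canonical order of
#' [feature_descriptors()]: PSSM (420), amino-acid factors (100), secondary
#' structure (63), solvent accessibility (42), disorder (21).
#'
#' @inheritParams block-encoders
#' @return A numeric vector of length 646, named by feature.
#' @export
assemble_features <- function(window, providers,
                              factor_table = atchley_factors()) {
  v <- c(encode_pssm(window, providers),
         encode_aafactors(window, factor_table),
         encode_secondary_structure(window, providers),
         encode_solvent_accessibility(window, providers),
         encode_disorder(window, providers))
  names(v) <- feature_names()
  v
}

#' Encode a table of peptide windows as a feature matrix
#'
#' @param windows A `peptide_windows` data frame.
#' @param providers A [provider_bundle()] covering every protein referenced
#'   by `windows`.
#' @param factor_table Amino-acid factor matrix, see [atchley_factors()].
#' @return A numeric matrix with one row per window and 646 columns in the
#'   order of [feature_descriptors()]; the descriptor table is attached as
#'   attribute `"descriptors"` and the window labels as attribute
#'   `"labels"`.
#' @export
encode_windows <- function(windows, providers,
                           factor_table = atchley_factors()) {
  df <- as.data.frame(windows)
  n <- nrow(df)
  desc <- feature_descriptors()
  out <- matrix(0, nrow = n, ncol = nrow(desc),
                dimnames = list(NULL, feature_names(desc)))
  for (i in seq_len(n)) {
    w <- df[i, , drop = FALSE]
    out[i, ] <- c(encode_pssm(w, providers),
                  encode_aafactors(w, factor_table),
                  encode_secondary_structure(w, providers),
                  encode_solvent_accessibility(w, providers),
                  encode_disorder(w, providers))
  }
  attr(out, "descriptors") <- desc
  attr(out, "labels") <- df$label
  out
}
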