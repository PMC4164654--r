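#' Load protein sequences and modification-site annotations
#'
#' Reads a multi-record FASTA file and a tab-separated site table with
#' columns `protein_id`, `position` (1-based residue index) and `mod_type`
#' (`"sumoylation"` or `"acetylation"`), and returns validated protein
#' records. Proteins whose sequences contain letters outside the 20 standard
#' amino acids are dropped with a warning, mirroring the curation step that
#' removes non-standard-residue proteins. Annotations are validated hard:
#' an unknown protein id, an out-of-range position, or a position whose
#' residue is not lysine ('K') is an error.
#'
#' @param fasta_source Path to a FASTA file.
#' @param site_table_source Path to a TSV file with header
#'   `protein_id`, `position`, `mod_type`.
#' @return A list of protein records; each is a list with elements `id`
#'   (character), `sequence` (character scalar) and `sites` (data.frame with
#'   columns `position`, `mod_type`). Records whose annotations all refer to
#'   dropped proteins are removed together with the protein. Records with
#'   zero sites are retained (they simply yield no windows).
#' @seealso [extract_windows()], [split_negatives()]
#' @export
load_annotations <- function(fasta_source, site_table_source) {
  fa <- seqinr::read.fasta(fasta_source, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  ids <- names(fa)
  seqs <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
  names(seqs) <- ids

  sites <- utils::read.delim(site_table_source, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "mod_type")
  if (!all(required %in% names(sites))) {
    stop("site table must have columns: ", paste(required, collapse = ", "))
  }
  sites$position <- as.integer(sites$position)
  bad_type <- setdiff(unique(sites$mod_type), c("sumoylation", "acetylation"))
  if (length(bad_type)) {
    stop("unknown mod_type value(s): ", paste(bad_type, collapse = ", "))
  }

  unknown <- setdiff(unique(sites$protein_id), ids)
  if (length(unknown)) {
    stop("site table references unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  }

  valid_letters <- amino_acids()
  records <- vector("list", length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    seq <- seqs[[id]]
    letters_i <- strsplit(seq, "")[[1]]
    if (!all(letters_i %in% valid_letters)) {
      warning("dropping protein '", id,
              "': sequence contains non-standard residues", call. = FALSE)
      next
    }
    st <- sites[sites$protein_id == id, c("position", "mod_type"),
                drop = FALSE]
    rownames(st) <- NULL
    if (nrow(st)) {
      out_of_range <- st$position < 1L | st$position > nchar(seq)
      if (any(out_of_range)) {
        stop("protein '", id, "': annotated position(s) ",
             paste(st$position[out_of_range], collapse = ", "),
             " outside sequence of length ", nchar(seq))
      }
      res <- letters_i[st$position]
      if (any(res != "K")) {
        stop("protein '", id, "': annotated position(s) ",
             paste(st$position[res != "K"], collapse = ", "),
             " are not lysine")
      }
    }
    records[[i]] <- protein_record(id, seq, st)
    keep[i] <- TRUE
  }
  records <- records[keep]
  dropped_with_sites <- setdiff(unique(sites$protein_id),
                                vapply(records, `[[`, character(1), "id"))
  if (length(dropped_with_sites)) {
    warning("annotations on dropped protein(s) discarded: ",
            paste(dropped_with_sites, collapse = ", "), call. = FALSE)
  }
  records
}

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (single string, 20 standard letters).
#' @param sites Data frame with columns `position` (1-based integer) and
#'   `mod_type` (`"sumoylation"` or `"acetylation"`).
#' @return A list of class `protein_record`.
#' @export
protein_record <- function(id, sequence,
                           sites = data.frame(position = integer(),
                                              mod_type = character())) {
  structure(list(id = as.character(id), sequence = as.character(sequence),
                 sites = sites),
            class = "protein_record")
}

#' Extract 21-residue peptide windows around annotated lysines
#'
#' One window is produced per annotated site: the central lysine at window
#' site 11 with 10 residues upstream and 10 downstream. Positions that fall
#' before the first or after the last residue are BLANK (encoded `NA` in the
#' slot matrix, written as `-` on disk); every downstream encoder maps BLANK
#' slots to all-zero features.
#'
#' @param record A `protein_record`, or a list of them.
#' @return A `peptide_windows` data frame with columns `protein_id`,
#'   `center_pos`, `label` (`"positive"` for sumoylation, `"negative"` for
#'   acetylation) and `s1`..`s21` slot letters (`NA` = BLANK).
#' @export
extract_windows <- function(record) {
  if (is.list(record) && !inherits(record, "protein_record")) {
    out <- lapply(record, extract_windows)
    return(do.call(rbind_windows, out))
  }
  stopifnot(inherits(record, "protein_record"))
  n_sites <- nrow(record$sites)
  slot_names <- paste0("s", seq_len(WINDOW_SIZE))
  if (n_sites == 0L) {
    df <- data.frame(protein_id = character(), center_pos = integer(),
                     label = character(), stringsAsFactors = FALSE)
    for (nm in slot_names) df[[nm]] <- character()
    return(as_peptide_windows(df))
  }
  letters_i <- strsplit(record$sequence, "")[[1]]
  len <- length(letters_i)
  slots_mat <- matrix(NA_character_, n_sites, WINDOW_SIZE)
  for (j in seq_len(n_sites)) {
    p <- record$sites$position[j]
    pos <- p + (seq_len(WINDOW_SIZE) - CENTER_SITE)
    in_range <- pos >= 1L & pos <= len
    slots_mat[j, in_range] <- letters_i[pos[in_range]]
  }
  df <- data.frame(
    protein_id = rep(record$id, n_sites),
    center_pos = as.integer(record$sites$position),
    label = ifelse(record$sites$mod_type == "sumoylation",
                   "positive", "negative"),
    stringsAsFactors = FALSE)
  df[slot_names] <- as.data.frame(slots_mat, stringsAsFactors = FALSE)
  as_peptide_windows(df)
}

as_peptide_windows <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("peptide_windows", "data.frame")
  df
}

rbind_windows <- function(...) {
  dfs <- list(...)
  as_peptide_windows(do.call(rbind, lapply(dfs, as.data.frame)))
}

#' Slot letters of peptide windows as a character matrix
#'
#' @param windows A `peptide_windows` data frame.
#' @return An n x 21 character matrix; `NA` marks BLANK slots.
#' @export
window_slots <- function(windows) {
  m <- as.matrix(as.data.frame(windows)[, paste0("s", seq_len(WINDOW_SIZE)),
                                        drop = FALSE])
  dimnames(m) <- list(NULL, paste0("s", seq_len(WINDOW_SIZE)))
  m
}

#' Split negative windows into balanced non-overlapping parts
#'
#' The negative (acetylation) class typically dwarfs the positive
#' (sumoylation) class; to form workable datasets the negatives are split
#' uniformly at random into `n_parts` disjoint parts whose sizes differ by at
#' most one (remainders go to the later parts, so 2780 negatives in 3 parts
#' give 926, 927, 927). Each returned partition bundles *all* positives with
#' one negative part.
#'
#' @param windows A `peptide_windows` data frame containing both classes.
#' @param n_parts Number of parts (>= 2).
#' @param seed Integer seed controlling the random permutation.
#' @return A list of `n_parts` partitions; each is a list with elements
#'   `name` (e.g. `"Dataset 1"`), `positives` and `negatives`
#'   (`peptide_windows` data frames).
#' @export
split_negatives <- function(windows, n_parts = 3L, seed) {
  stopifnot(n_parts >= 2L)
  df <- as.data.frame(windows)
  pos <- df[df$label == "positive", , drop = FALSE]
  neg <- df[df$label == "negative", , drop = FALSE]
  n_neg <- nrow(neg)
  if (n_neg < n_parts) {
    stop("fewer negatives (", n_neg, ") than parts (", n_parts, ")")
  }
  base <- n_neg %/% n_parts
  rem <- n_neg %% n_parts
  # remainders are assigned to the later parts: sizes like 926, 927, 927
  sizes <- rep(base, n_parts) + c(rep(0L, n_parts - rem), rep(1L, rem))
  perm <- withr::with_seed(seed, sample.int(n_neg))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_parts), function(i) {
    idx <- perm[starts[i]:ends[i]]
    list(name = paste("Dataset", i),
         positives = as_peptide_windows(pos),
         negatives = as_peptide_windows(neg[sort(idx), , drop = FALSE]))
  })
}

#' Combine a partition's positives and negatives into one window table
#'
#' @param partition One element of the list returned by [split_negatives()].
#' @return A `peptide_windows` data frame (positives first).
#' @export
partition_windows <- function(partition) {
  rbind_windows(partition$positives, partition$negatives)
}

#' Read and write peptide-window tables
#'
#' Windows are stored as TSV with columns `protein_id`, `center_pos`,
#' `label`, and 21 slot letters `s1`..`s21` with `-` for BLANK.
#'
#' @param windows A `peptide_windows` data frame.
#' @param path File path.
#' @return `read_windows()` returns a `peptide_windows` data frame;
#'   `write_windows()` returns `path` invisibly.
#' @export
write_windows <- function(windows, path) {
  df <- as.data.frame(windows)
  slot_cols <- paste0("s", seq_len(WINDOW_SIZE))
  for (nm in slot_cols) df[[nm]][is.na(df[[nm]])] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$center_pos <- as.integer(df$center_pos)
  slot_cols <- paste0("s", seq_len(WINDOW_SIZE))
  for (nm in slot_cols) df[[nm]][df[[nm]] == "-"] <- NA_character_
  as_peptide_windows(df)
}
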