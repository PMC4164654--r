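#' Bundle per-residue feature provider tables
#'
#' The encoders consume four per-residue annotation tracks per protein:
#' PSSM conservation scores (one row of 20 scores per residue, columns in
#' the order of [amino_acids()]), a 3-state secondary-structure string over
#' `H` (helix), `E` (strand), `O` (other), a 2-state solvent-accessibility
#' string over `B` (buried), `X` (exposed), and a per-residue disorder score
#' in \[0, 1\]. All four tracks of a protein must have the same length; the
#' length is taken as the protein's sequence length.
#'
#' @param pssm Named list of numeric matrices (rows = residues, 20 columns).
#' @param ss Named character vector of secondary-structure strings.
#' @param sa Named character vector of solvent-accessibility strings.
#' @param disorder Named list of numeric vectors with values in \[0, 1\].
#' @return A list of class `provider_bundle`.
#' @export
provider_bundle <- function(pssm, ss, sa, disorder) {
  ids <- names(pssm)
  stopifnot(!is.null(ids),
            setequal(ids, names(ss)), setequal(ids, names(sa)),
            setequal(ids, names(disorder)))
  for (id in ids) {
    len <- nrow(pssm[[id]])
    lens <- c(pssm = len, ss = nchar(ss[[id]]), sa = nchar(sa[[id]]),
              disorder = length(disorder[[id]]))
    if (length(unique(lens)) != 1L) {
      stop("provider length mismatch for protein '", id, "': ",
           paste(names(lens), lens, sep = "=", collapse = ", "))
    }
    if (ncol(pssm[[id]]) != 20L) {
      stop("PSSM for protein '", id, "' must have 20 columns, has ",
           ncol(pssm[[id]]))
    }
    bad_ss <- setdiff(strsplit(ss[[id]], "")[[1]], c("H", "E", "O"))
    if (length(bad_ss)) {
      stop("unknown secondary-structure state(s) for '", id, "': ",
           paste(bad_ss, collapse = ", "))
    }
    bad_sa <- setdiff(strsplit(sa[[id]], "")[[1]], c("B", "X"))
    if (length(bad_sa)) {
      stop("unknown solvent-accessibility state(s) for '", id, "': ",
           paste(bad_sa, collapse = ", "))
    }
    d <- disorder[[id]]
    if (any(d < 0 | d > 1)) {
      stop("disorder scores for '", id, "' must lie in [0, 1]")
    }
  }
  structure(list(pssm = pssm, ss = ss, sa = sa, disorder = disorder),
            class = "provider_bundle")
}

#' Read provider tables from their TSV dialects
#'
#' `read_pssm_tsv()` reads a long-format PSSM table (`protein_id`,
#' `position`, then 20 amino-acid columns), `read_ss_tsv()` and
#' `read_sa_tsv()` read per-protein state strings (`protein_id`, `ss` /
#' `sa`), and `read_disorder_tsv()` reads per-residue scores (`protein_id`,
#' `position`, `score`). `read_providers()` reads all four and assembles a
#' validated [provider_bundle()].
#'
#' @param path File path.
#' @return `read_pssm_tsv()`: named list of n x 20 matrices;
#'   `read_ss_tsv()`/`read_sa_tsv()`: named character vector;
#'   `read_disorder_tsv()`: named list of numeric vectors.
#' @name provider-io
#' @export
read_pssm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  aa <- amino_acids()
  stopifnot(all(c("protein_id", "position", aa) %in% names(df)))
  out <- lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("PSSM positions for protein '", d$protein_id[1],
           "' are not contiguous from 1")
    }
    m <- as.matrix(d[, aa, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  out
}

#' @rdname provider-io
#' @export
read_ss_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "ss") %in% names(df)))
  stats::setNames(df$ss, df$protein_id)
}

#' @rdname provider-io
#' @export
read_sa_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "sa") %in% names(df)))
  stats::setNames(df$sa, df$protein_id)
}

#' @rdname provider-io
#' @export
read_disorder_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "score") %in% names(df)))
  lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    as.numeric(d$score)
  })
}

#' @rdname provider-io
#' @param pssm_path,ss_path,sa_path,disorder_path Paths to the four tables.
#' @export
read_providers <- function(pssm_path, ss_path, sa_path, disorder_path) {
  provider_bundle(pssm = read_pssm_tsv(pssm_path),
                  ss = read_ss_tsv(ss_path),
                  sa = read_sa_tsv(sa_path),
                  disorder = read_disorder_tsv(disorder_path))
}

#' Read a PSI-BLAST ASCII PSSM dump
#'
#' Parses the plain-text matrix written by `psiblast -out_ascii_pssm`: data
#' lines carry a residue index, the residue letter, 20 log-odds columns,
#' 20 weighted-percentage columns and two trailing statistics. Only the 20
#' log-odds columns are retained, reordered from the PSI-BLAST header order
#' to the alphabetical order of [amino_acids()].
#'
#' @param path Path to the ASCII PSSM file.
#' @return An n x 20 numeric matrix (rows = residues, columns =
#'   [amino_acids()]).
#' @export
read_pssm_psiblast <- function(path) {
  lines <- readLines(path)
  header_idx <- NULL
  header_order <- NULL
  rows <- list()
  res_letters <- character()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "") next
    if (is.null(header_order) && length(tok) >= 20 &&
        all(tok[1:20] %in% amino_acids())) {
      # column header line: 20 (log-odds) + usually 20 more (percentages)
      header_order <- tok[1:20]
      next
    }
    if (!is.null(header_order) && length(tok) >= 22 &&
        grepl("^[0-9]+$", tok[1]) && tok[2] %in% amino_acids()) {
      vals <- suppressWarnings(as.numeric(tok[3:22]))
      if (anyNA(vals)) next
      rows[[length(rows) + 1L]] <- vals
      res_letters <- c(res_letters, tok[2])
    }
  }
  if (is.null(header_order) || !length(rows)) {
    stop("no PSSM rows found in '", path, "'")
  }
  m <- do.call(rbind, rows)
  colnames(m) <- header_order
  m <- m[, amino_acids(), drop = FALSE]
  rownames(m) <- NULL
  attr(m, "residues") <- res_letters
  m
}

#' Write provider tables in the TSV dialects read by [read_providers()]
#'
#' @param providers A [provider_bundle()].
#' @param pssm_path,ss_path,sa_path,disorder_path Output paths.
#' @return Invisibly, a character vector of the four paths.
#' @export
write_providers <- function(providers, pssm_path, ss_path, sa_path,
                            disorder_path) {
  ids <- names(providers$pssm)
  pssm_df <- do.call(rbind, lapply(ids, function(id) {
    m <- providers$pssm[[id]]
    d <- data.frame(protein_id = rep(id, nrow(m)),
                    position = seq_len(nrow(m)), stringsAsFactors = FALSE)
    cbind(d, as.data.frame(m) |> stats::setNames(amino_acids()))
  }))
  utils::write.table(pssm_df, pssm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = ids, ss = unname(providers$ss[ids])),
    ss_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = ids, sa = unname(providers$sa[ids])),
    sa_path, sep = "\t", quote = FALSE, row.names = FALSE)
  dis_df <- do.call(rbind, lapply(ids, function(id) {
    data.frame(protein_id = id,
               position = seq_along(providers$disorder[[id]]),
               score = providers$disorder[[id]], stringsAsFactors = FALSE)
  }))
  utils::write.table(dis_df, disorder_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pssm_path, ss_path, sa_path, disorder_path))
}
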