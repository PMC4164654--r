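#' Configuration for the synthetic window-dataset generator
#'
#' The generator emulates the statistical structure of a curated
#' sumoylation/acetylation window dataset: a small positive class carrying
#' a \eqn{\Psi}KXE-like motif (an aliphatic residue V/I/L immediately
#' upstream of the lysine — window site 10 — and a glutamate two residues
#' downstream — site 13), a large negative class with lysine-enriched
#' flanks, and class-dependent secondary-structure, disorder and PSSM
#' distributions concentrated at the same "hot" sites. All effect sizes are
#' configuration, not constants.
#'
#' @param n_pos,n_neg Number of positive (sumoylation) and negative
#'   (acetylation) windows; defaults emulate the 218/2780 class imbalance
#'   of the curated dataset.
#' @param seed Integer seed; the same configuration always generates
#'   byte-identical output.
#' @param motif_prob Probability that a positive window carries the motif
#'   (V/I/L at site 10 and E at site 13).
#' @param neg_K_enrichment Excess lysine probability in negative flanks,
#'   added to the background K frequency and renormalized.
#' @param background Named 20-vector of amino-acid frequencies (sums to 1);
#'   defaults to Swiss-Prot-like composition.
#' @param ss_class_shift `NULL`, or a list with elements `site`, `state`,
#'   `delta`, `from`: for positive windows, `delta` probability mass is
#'   moved from secondary-structure state `from` to `state` at the given
#'   window site. Default: +0.2 to `other` at site 13, taken from `helix`.
#' @param sa_class_shift `NULL` (default), or a list with elements `site`,
#'   `state` (`"buried"`/`"exposed"`), `delta`: analogous shift of the
#'   solvent-accessibility distribution for positives.
#' @param disorder_means Length-2 vector `c(positive, negative)`: mean of
#'   the per-residue disorder Beta distribution at `disorder_sites`.
#' @param disorder_sites Window sites whose disorder distribution is
#'   class-dependent; elsewhere the mean is 0.5 for both classes.
#' @param disorder_precision Beta precision (a + b); larger is less noisy.
#' @param pssm_match,pssm_mismatch Mean log-odds score of a PSSM column
#'   matching / not matching the residue at that position.
#' @param pssm_class_delta Additional mean log-odds added, for positive
#'   windows only, to the motif columns (V, I, L at site 10; E at site 13),
#'   modelling evolutionary conservation of the sumoylation motif.
#' @param pssm_noise_sd Standard deviation of the Gaussian noise on every
#'   PSSM entry.
#' @param terminal_prob Probability that a window is placed near a protein
#'   terminus (fewer than 10 flanking residues on one side), exercising the
#'   BLANK-padding path.
#' @return A list of class `generator_config`.
#' @seealso [generate_dataset()], [planted_descriptors()]
#' @export
generator_config <- function(n_pos = 218L, n_neg = 2780L, seed = 1L,
                             motif_prob = 0.8,
                             neg_K_enrichment = 0.10,
                             background = NULL,
                             ss_class_shift = list(site = 13L,
                                                   state = "other",
                                                   delta = 0.2,
                                                   from = "helix"),
                             sa_class_shift = NULL,
                             disorder_means = c(positive = 0.65,
                                                negative = 0.55),
                             disorder_sites = c(9L, 10L, 13L),
                             disorder_precision = 10,
                             pssm_match = 3, pssm_mismatch = -1,
                             pssm_class_delta = 2, pssm_noise_sd = 1,
                             terminal_prob = 0.1) {
  if (is.null(background)) background <- swissprot_background()
  stopifnot(n_pos >= 2L, n_neg >= 2L,
            motif_prob >= 0, motif_prob <= 1,
            neg_K_enrichment >= 0, neg_K_enrichment <= 1,
            terminal_prob >= 0, terminal_prob <= 1,
            length(background) == 20L,
            abs(sum(background) - 1) < 1e-8,
            all(background >= 0),
            all(disorder_means >= 0 & disorder_means <= 1),
            pssm_noise_sd >= 0, disorder_precision > 0)
  if (!is.null(ss_class_shift)) {
    stopifnot(ss_class_shift$state %in% c("helix", "strand", "other"),
              ss_class_shift$from %in% c("helix", "strand", "other"),
              ss_class_shift$delta >= 0, ss_class_shift$delta <= 1)
  }
  if (!is.null(sa_class_shift)) {
    stopifnot(sa_class_shift$state %in% c("buried", "exposed"),
              sa_class_shift$delta >= 0, sa_class_shift$delta <= 1)
  }
  names(background) <- amino_acids()
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seed = as.integer(seed), motif_prob = motif_prob,
                 neg_K_enrichment = neg_K_enrichment,
                 background = background,
                 ss_class_shift = ss_class_shift,
                 sa_class_shift = sa_class_shift,
                 disorder_means = stats::setNames(disorder_means,
                                                  c("positive", "negative")),
                 disorder_sites = as.integer(disorder_sites),
                 disorder_precision = disorder_precision,
                 pssm_match = pssm_match, pssm_mismatch = pssm_mismatch,
                 pssm_class_delta = pssm_class_delta,
                 pssm_noise_sd = pssm_noise_sd,
                 terminal_prob = terminal_prob),
            class = "generator_config")
}

#' Swiss-Prot-like background amino-acid frequencies
#'
#' @return Named numeric vector over [amino_acids()], summing to 1.
#' @export
swissprot_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.63, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f <- f[amino_acids()]
  f / sum(f)
}

ss_states <- c(helix = "H", strand = "E", other = "O")
sa_states <- c(buried = "B", exposed = "X")

# Per-site categorical distributions for one window's class.
ss_site_probs <- function(config, positive, site) {
  p <- c(helix = 0.3, strand = 0.2, other = 0.5)
  sh <- config$ss_class_shift
  if (positive && !is.null(sh) && site == sh$site) {
    p[sh$state] <- p[sh$state] + sh$delta
    p[sh$from] <- p[sh$from] - sh$delta
  }
  p
}

sa_site_probs <- function(config, positive, site) {
  p <- c(buried = 0.5, exposed = 0.5)
  sh <- config$sa_class_shift
  if (positive && !is.null(sh) && site == sh$site) {
    other_state <- setdiff(names(p), sh$state)
    p[sh$state] <- p[sh$state] + sh$delta
    p[other_state] <- p[other_state] - sh$delta
  }
  p
}

#' Generate a synthetic sumoylation/acetylation window dataset
#'
#' One protein is generated per window: the 21-residue window embedded in
#' random flanks, with the annotated lysine at the center. With probability
#' `terminal_prob` the site is placed near a terminus so that the window is
#' truncated and the BLANK-padding path is exercised. All four provider
#' tracks (PSSM, secondary structure, solvent accessibility, disorder)
#' cover the full protein length and are written in the exact dialects the
#' encoders read, so the generator doubles as a format fixture.
#'
#' @param config A [generator_config()].
#' @return A list of class `ptm_simulation` with components `records`
#'   (list of [protein_record()]), `sites` (data frame: `protein_id`,
#'   `position`, `mod_type`), `providers` (a [provider_bundle()]) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  aa <- amino_acids()
  n_total <- config$n_pos + config$n_neg
  positive <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
  ids <- sprintf("SYN%04d", seq_len(n_total))

  bg_pos <- config$background
  bg_neg <- config$background
  bg_neg["K"] <- bg_neg["K"] + config$neg_K_enrichment
  bg_neg <- bg_neg / sum(bg_neg)

  records <- vector("list", n_total)
  pssm <- vector("list", n_total)
  ss <- character(n_total)
  sa <- character(n_total)
  disorder <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    pos_i <- positive[i]
    bg <- if (pos_i) bg_pos else bg_neg

    # flank geometry: near-terminus windows are truncated on one side
    left <- 10L + sample(0:15, 1L)
    right <- 10L + sample(0:15, 1L)
    if (stats::runif(1) < config$terminal_prob) {
      if (stats::runif(1) < 0.5) left <- sample(0:9, 1L) else
        right <- sample(0:9, 1L)
    }
    len <- left + 1L + right
    center <- left + 1L

    seq_letters <- sample(aa, len, replace = TRUE, prob = bg)
    seq_letters[center] <- "K"
    if (pos_i && stats::runif(1) < config$motif_prob) {
      # window site 10 = center - 1 (aliphatic), site 13 = center + 2 (E)
      if (center - 1L >= 1L) {
        seq_letters[center - 1L] <- sample(c("V", "I", "L"), 1L)
      }
      if (center + 2L <= len) seq_letters[center + 2L] <- "E"
    }

    # which window site (1..21) each residue occupies, NA outside the window
    site_of <- rep(NA_integer_, len)
    wpos <- center + (seq_len(WINDOW_SIZE) - CENTER_SITE)
    ok <- wpos >= 1L & wpos <= len
    site_of[wpos[ok]] <- which(ok)

    # PSSM: residue-dependent mean log-odds plus motif conservation delta
    m <- matrix(config$pssm_mismatch, nrow = len, ncol = 20L,
                dimnames = list(NULL, aa))
    m[cbind(seq_len(len), match(seq_letters, aa))] <- config$pssm_match
    if (pos_i && config$pssm_class_delta != 0) {
      r10 <- which(site_of == 10L)
      if (length(r10)) {
        m[r10, c("V", "I", "L")] <- m[r10, c("V", "I", "L")] +
          config$pssm_class_delta
      }
      r13 <- which(site_of == 13L)
      if (length(r13)) m[r13, "E"] <- m[r13, "E"] + config$pssm_class_delta
    }
    m <- m + matrix(stats::rnorm(len * 20L, sd = config$pssm_noise_sd),
                    len, 20L)

    # secondary structure / solvent accessibility strings
    ss_i <- character(len)
    sa_i <- character(len)
    for (r in seq_len(len)) {
      site <- if (is.na(site_of[r])) 0L else site_of[r]
      ps <- ss_site_probs(config, pos_i, site)
      ss_i[r] <- ss_states[sample(names(ps), 1L, prob = ps)]
      pa <- sa_site_probs(config, pos_i, site)
      sa_i[r] <- sa_states[sample(names(pa), 1L, prob = pa)]
    }

    # disorder: class-dependent Beta mean at the configured hot sites
    mu <- rep(0.5, len)
    hot <- which(site_of %in% config$disorder_sites)
    if (length(hot)) {
      mu[hot] <- config$disorder_means[if (pos_i) "positive" else "negative"]
    }
    phi <- config$disorder_precision
    d_i <- stats::rbeta(len, shape1 = mu * phi, shape2 = (1 - mu) * phi)

    records[[i]] <- protein_record(
      ids[i], paste(seq_letters, collapse = ""),
      data.frame(position = center,
                 mod_type = if (pos_i) "sumoylation" else "acetylation",
                 stringsAsFactors = FALSE))
    pssm[[i]] <- m
    ss[i] <- paste(ss_i, collapse = "")
    sa[i] <- paste(sa_i, collapse = "")
    disorder[[i]] <- d_i
  }

  names(pssm) <- ids
  names(ss) <- ids
  names(sa) <- ids
  names(disorder) <- ids

  sites <- do.call(rbind, lapply(records, function(r) {
    data.frame(protein_id = r$id, position = r$sites$position,
               mod_type = r$sites$mod_type, stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  structure(list(records = records, sites = sites,
                 providers = provider_bundle(pssm, ss, sa, disorder),
                 config = config),
            class = "ptm_simulation")
}

#' Ground-truth informative feature descriptors of a generator config
#'
#' Lists the feature descriptors whose generating distributions are
#' configured to differ between the classes — the planted signal that
#' parameter-recovery tests compare against: the PSSM motif columns
#' (V/I/L at site 10, E at site 13) when the motif or its conservation
#' delta is active, the shifted secondary-structure (and, if configured,
#' solvent-accessibility) states, and the disorder scores at the hot
#' sites. Amino-acid factor columns at the motif sites inherit signal from
#' the sequence motif but are a deterministic re-encoding of the same
#' residues, so they are not listed separately.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `block`, `site`, `subtype`; zero rows
#'   when no parameter separates the classes.
#' @export
planted_descriptors <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rows <- list()
  if (config$motif_prob > 0 || config$pssm_class_delta != 0) {
    rows <- c(rows, list(
      data.frame(block = "PSSM", site = 10L, subtype = c("V", "I", "L"),
                 stringsAsFactors = FALSE),
      data.frame(block = "PSSM", site = 13L, subtype = "E",
                 stringsAsFactors = FALSE)))
  }
  sh <- config$ss_class_shift
  if (!is.null(sh) && sh$delta > 0) {
    rows <- c(rows, list(
      data.frame(block = "SecondaryStructure", site = as.integer(sh$site),
                 subtype = c(sh$state, sh$from), stringsAsFactors = FALSE)))
  }
  sha <- config$sa_class_shift
  if (!is.null(sha) && sha$delta > 0) {
    rows <- c(rows, list(
      data.frame(block = "SolventAccessibility",
                 site = as.integer(sha$site),
                 subtype = c("buried", "exposed"),
                 stringsAsFactors = FALSE)))
  }
  if (config$disorder_means["positive"] != config$disorder_means["negative"]) {
    rows <- c(rows, list(
      data.frame(block = "Disorder", site = config$disorder_sites,
                 subtype = "score", stringsAsFactors = FALSE)))
  }
  if (!length(rows)) {
    return(data.frame(block = character(), site = integer(),
                      subtype = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTA file, the site table and the four provider tables in the
#' formats consumed by [load_annotations()] and [read_providers()].
#'
#' @param sim A `ptm_simulation` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the six file paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ptm_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             sites = file.path(dir, "sites.tsv"),
             pssm = file.path(dir, "pssm.tsv"),
             ss = file.path(dir, "ss.tsv"),
             sa = file.path(dir, "sa.tsv"),
             disorder = file.path(dir, "disorder.tsv"))
  seqinr::write.fasta(
    sequences = lapply(sim$records, function(r) r$sequence),
    names = vapply(sim$records, `[[`, character(1), "id"),
    file.out = paths["fasta"], as.string = TRUE, nbchar = 60)
  utils::write.table(sim$sites, paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_providers(sim$providers, paths["pssm"], paths["ss"], paths["sa"],
                  paths["disorder"])
  invisible(paths)
}
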