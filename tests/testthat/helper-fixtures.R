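# Small fixtures built in code, plus a session cache for the one expensive
# simulated dataset shared by several test files.

# A single-protein fixture with hand-controllable providers. The protein is
# 30 residues with a K at the requested position.
make_fixture <- function(k_pos = 15, len = 30, mod = "sumoylation") {
  letters30 <- rep(c("A", "R", "N", "D", "C", "Q"), length.out = len)
  letters30[k_pos] <- "K"
  seq <- paste(letters30, collapse = "")
  rec <- protein_record("prot1", seq,
                        data.frame(position = k_pos, mod_type = mod,
                                   stringsAsFactors = FALSE))
  pssm <- matrix(seq_len(len * 20), nrow = len, ncol = 20)
  ss <- paste(rep(c("H", "E", "O"), length.out = len), collapse = "")
  sa <- paste(rep(c("B", "X"), length.out = len), collapse = "")
  disorder <- seq(0, 1, length.out = len)
  providers <- provider_bundle(
    pssm = list(prot1 = pssm),
    ss = c(prot1 = ss),
    sa = c(prot1 = sa),
    disorder = list(prot1 = disorder))
  list(record = rec, providers = providers,
       windows = extract_windows(rec))
}

# Build a bare peptide_windows data frame from a character matrix of slots
# (NA = BLANK) and a label vector, bypassing extraction.
make_windows_df <- function(slots, labels,
                            protein_id = sprintf("W%03d", seq_len(nrow(slots))),
                            center_pos = 11L) {
  df <- data.frame(protein_id = protein_id,
                   center_pos = rep(center_pos, nrow(slots)),
                   label = labels, stringsAsFactors = FALSE)
  colnames(slots) <- paste0("s", 1:21)
  df <- cbind(df, as.data.frame(slots, stringsAsFactors = FALSE))
  class(df) <- c("peptide_windows", "data.frame")
  df
}

# Session cache: the 150+150 simulated dataset with encoded features and
# mRMR ranking, used by the recovery tests and the regression invariant.
recovery_cache <- new.env(parent = emptyenv())

get_recovery_data <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  cfg <- generator_config(n_pos = 150L, n_neg = 150L, seed = seed)
  sim <- generate_dataset(cfg)
  windows <- extract_windows(sim$records)
  features <- encode_windows(windows, sim$providers)
  ranking <- mrmr_rank(features)
  recovery_cache[[key]] <- list(config = cfg, sim = sim, windows = windows,
                                features = features, ranking = ranking)
  recovery_cache[[key]]
}

descriptor_key <- function(d) paste(d$block, d$site, d$subtype, sep = "|")
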