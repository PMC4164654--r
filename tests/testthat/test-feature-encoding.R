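test_that("descriptor table has the canonical block structure", {
  desc <- feature_descriptors()
  expect_equal(nrow(desc), 646)
  counts <- table(desc$block)
  expect_equal(unname(counts[c("PSSM", "AAFactor", "SecondaryStructure",
                               "SolventAccessibility", "Disorder")]),
               c(420L, 100L, 63L, 42L, 21L), ignore_attr = TRUE)
  expect_false(any(desc$block == "AAFactor" & desc$site == 11))
  expect_equal(desc$index, seq_len(646))
  # slot-major within blocks: PSSM site of column j is ceiling(j / 20)
  pssm <- desc[desc$block == "PSSM", ]
  expect_equal(pssm$site, rep(1:21, each = 20))
  expect_equal(pssm$subtype, rep(amino_acids(), 21))
})

test_that("PSSM encoding passes provider rows through in slot-major order", {
  fx <- make_fixture(k_pos = 15, len = 40)
  fx$providers$pssm$prot1[10, ] <- 1:20  # residue 10 = window slot 6
  v <- encode_pssm(fx$windows[1, ], fx$providers)
  expect_length(v, 420)
  expect_equal(v[(6 - 1) * 20 + 1:20], 1:20)

  # truncated window: BLANK slots are 20 zeros
  fx5 <- make_fixture(k_pos = 5)
  v5 <- encode_pssm(fx5$windows[1, ], fx5$providers)
  expect_equal(v5[1:(6 * 20)], rep(0, 120))
  expect_false(all(v5[121:420] == 0))

  # provider too short for the window: error naming the protein
  short <- fx$providers
  short$pssm$prot1 <- short$pssm$prot1[1:20, ]
  short$ss <- c(prot1 = substr(short$ss[["prot1"]], 1, 20))
  short$sa <- c(prot1 = substr(short$sa[["prot1"]], 1, 20))
  short$disorder <- list(prot1 = short$disorder$prot1[1:20])
  expect_error(encode_pssm(fx$windows[1, ], short), "prot1")
})

test_that("amino-acid factor encoding skips the center and uses the table", {
  slots <- matrix("A", 1, 21)
  slots[1, 11] <- "K"
  w <- make_windows_df(slots, "positive")
  v <- encode_aafactors(w[1, ])
  expect_length(v, 100)
  expected <- unname(atchley_factors()["A", ])
  for (i in 1:20) expect_equal(v[(i - 1) * 5 + 1:5], expected,
                               ignore_attr = TRUE)
  # K's row appears nowhere: all 20 tuples are A's values
  expect_false(any(abs(v - rep(expected, 20)) > 1e-12))

  # BLANK flanks encode as zeros
  slots2 <- matrix(NA_character_, 1, 21)
  slots2[1, 11] <- "K"
  w2 <- make_windows_df(slots2, "positive")
  expect_equal(encode_aafactors(w2[1, ]), rep(0, 100))
})

test_that("secondary structure and accessibility are one-hot coded", {
  fx <- make_fixture(k_pos = 15, len = 40)
  # fixture ss cycles H,E,O starting at residue 1; window slot s covers
  # residue 15 + (s - 11)
  v <- encode_secondary_structure(fx$windows[1, ], fx$providers)
  expect_length(v, 63)
  states <- strsplit(fx$providers$ss[["prot1"]], "")[[1]]
  for (s in 1:21) {
    triple <- v[(s - 1) * 3 + 1:3]
    expect_equal(sum(triple), 1)
    expected <- c(H = 1, E = 2, O = 3)[states[15 + s - 11]]
    expect_equal(which(triple == 1), unname(expected))
  }

  va <- encode_solvent_accessibility(fx$windows[1, ], fx$providers)
  expect_length(va, 42)
  sa_states <- strsplit(fx$providers$sa[["prot1"]], "")[[1]]
  for (s in 1:21) {
    pair <- va[(s - 1) * 2 + 1:2]
    expect_equal(sum(pair), 1)
    expect_equal(which(pair == 1),
                 unname(c(B = 1, X = 2)[sa_states[15 + s - 11]]))
  }

  # BLANK slots are all-zero in both blocks
  fx5 <- make_fixture(k_pos = 5)
  v5 <- encode_secondary_structure(fx5$windows[1, ], fx5$providers)
  expect_equal(v5[1:18], rep(0, 18))
  va5 <- encode_solvent_accessibility(fx5$windows[1, ], fx5$providers)
  expect_equal(va5[1:12], rep(0, 12))
})

test_that("disorder encoding copies scores and zeros BLANK slots", {
  fx <- make_fixture(k_pos = 15, len = 40)
  v <- encode_disorder(fx$windows[1, ], fx$providers)
  expect_length(v, 21)
  expect_equal(v, fx$providers$disorder$prot1[15 + (1:21) - 11])

  fx5 <- make_fixture(k_pos = 5)
  v5 <- encode_disorder(fx5$windows[1, ], fx5$providers)
  expect_equal(v5[1:6], rep(0, 6))
  expect_equal(v5[7:21], fx5$providers$disorder$prot1[1:15])
})

test_that("assembled vectors have 646 features and are pure functions", {
  fx <- make_fixture(k_pos = 15, len = 40)
  v1 <- assemble_features(fx$windows[1, ], fx$providers)
  v2 <- assemble_features(fx$windows[1, ], fx$providers)
  expect_length(v1, 646)
  expect_identical(v1, v2)

  # padding does not change the length
  fx5 <- make_fixture(k_pos = 5)
  expect_length(assemble_features(fx5$windows[1, ], fx5$providers), 646)
})

test_that("any value read back through its descriptor matches the provider", {
  withr::with_seed(42, {
    sim <- generate_dataset(generator_config(n_pos = 4, n_neg = 4, seed = 3))
    windows <- extract_windows(sim$records)
    X <- encode_windows(windows, sim$providers)
    desc <- attr(X, "descriptors")
    slots <- window_slots(windows)
    aa <- amino_acids()
    for (i in seq_len(nrow(windows))) {
      pid <- windows$protein_id[i]
      center <- windows$center_pos[i]
      for (j in sample(646, 80)) {
        d <- desc[j, ]
        pos <- center + (d$site - 11)
        blank <- is.na(slots[i, d$site])
        val <- X[i, j]
        if (blank) {
          expect_equal(unname(val), 0)
          next
        }
        raw <- switch(d$block,
          PSSM = sim$providers$pssm[[pid]][pos, match(d$subtype, aa)],
          AAFactor = atchley_factors()[slots[i, d$site], d$subtype],
          SecondaryStructure = as.numeric(
            substr(sim$providers$ss[[pid]], pos, pos) ==
              c(helix = "H", strand = "E", other = "O")[d$subtype]),
          SolventAccessibility = as.numeric(
            substr(sim$providers$sa[[pid]], pos, pos) ==
              c(buried = "B", exposed = "X")[d$subtype]),
          Disorder = sim$providers$disorder[[pid]][pos])
        expect_equal(unname(val), unname(raw))
      }
    }
  })
})

test_that("per-slot one-hot groups are consistent across random windows", {
  sim <- generate_dataset(generator_config(n_pos = 5, n_neg = 5, seed = 8,
                                           terminal_prob = 0.5))
  windows <- extract_windows(sim$records)
  X <- encode_windows(windows, sim$providers)
  desc <- attr(X, "descriptors")
  slots <- window_slots(windows)
  for (i in seq_len(nrow(windows))) {
    for (s in 1:21) {
      ss_idx <- desc$index[desc$block == "SecondaryStructure" &
                             desc$site == s]
      sa_idx <- desc$index[desc$block == "SolventAccessibility" &
                             desc$site == s]
      if (is.na(slots[i, s])) {
        all_idx <- desc$index[desc$site == s]
        expect_true(all(X[i, all_idx] == 0))
      } else {
        expect_equal(sum(X[i, ss_idx]), 1)
        expect_equal(sum(X[i, sa_idx]), 1)
      }
    }
  }
})

test_that("PSI-BLAST ASCII PSSM dumps are parsed and reordered", {
  path <- withr::local_tempfile(fileext = ".pssm")
  header <- c("",
    "Last position-specific scoring matrix computed, weighted observed...",
    paste0("            ",
           paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                 collapse = "  "), "   ",
           paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                 collapse = "  ")))
  row1 <- paste(c("    1 M ", sprintf("%d", 1:20),
                  rep("0", 20), " 0.35 0.07"), collapse = " ")
  row2 <- paste(c("    2 K ", sprintf("%d", 21:40),
                  rep("0", 20), " 0.35 0.07"), collapse = " ")
  writeLines(c(header, row1, row2, "", "Lambda  K"), path)
  m <- read_pssm_psiblast(path)
  expect_equal(dim(m), c(2, 20))
  expect_equal(colnames(m), amino_acids())
  # input row 1 scores 1..20 in PSI-BLAST order: A=1, R=2, ..., V=20
  expect_equal(unname(m[1, "A"]), 1)
  expect_equal(unname(m[1, "R"]), 2)
  expect_equal(unname(m[1, "V"]), 20)
  expect_equal(unname(m[2, "A"]), 21)
  expect_equal(attr(m, "residues"), c("M", "K"))
})

test_that("provider bundles validate lengths and alphabets", {
  expect_error(provider_bundle(
    pssm = list(p = matrix(0, 5, 20)), ss = c(p = "HHHH"),
    sa = c(p = "BXBXB"), disorder = list(p = rep(0.5, 5))),
    "length mismatch")
  expect_error(provider_bundle(
    pssm = list(p = matrix(0, 4, 20)), ss = c(p = "HHQZ"),
    sa = c(p = "BXBX"), disorder = list(p = rep(0.5, 4))),
    "secondary-structure")
  expect_error(provider_bundle(
    pssm = list(p = matrix(0, 4, 20)), ss = c(p = "HHEO"),
    sa = c(p = "BXBX"), disorder = list(p = c(0.5, 0.5, 0.5, 1.5))),
    "disorder")
})
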