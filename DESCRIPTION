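Package: sumoacet
Title: Discriminating Lysine Sumoylation from Lysine Acetylation by
    mRMR and Incremental Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discriminate sumoylated from acetylated lysine
    residues from sequence-derived features. Extracts 21-residue peptide
    windows around annotated modification sites, encodes each window with
    646 features drawn from five blocks (PSSM conservation scores, Atchley
    amino-acid factors, three-state secondary structure, two-state solvent
    accessibility, and per-residue disorder scores), ranks features by the
    maximum-relevance minimum-redundancy (mRMR) difference criterion, and
    selects an optimal feature subset by incremental feature selection under
    cross-validated random-forest classification scored by the Matthews
    correlation coefficient. Includes analysis utilities for optimal feature
    sets (type, site and subtype distributions, positional amino-acid
    frequency matrices) and a synthetic-data generator that emulates the
    class structure of sumoylation/acetylation window datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    seqinr,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
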