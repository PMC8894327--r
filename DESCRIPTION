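Package: gecxms
Title: Cross-Link Search and Simulation for Genetically Encoded Chemical Cross-Linking MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies peptide pairs cross-linked through a genetically encoded
    alkyl-bromide non-canonical amino acid from centroided tandem-MS peak lists.
    Implements monoisotopic mass arithmetic, in-silico single and sequential
    (Lys-C then trypsin) protease digestion, FASTA/MGF/mzML readers, a
    mass-indexed two-chain b/y search engine with binomial-tail scoring and
    cross-link-site localization over an eight-residue nucleophile set
    (C, D, E, H, K, S, T, Y), target-decoy false discovery rate control,
    per-residue reactivity summaries, motif-window extraction with position
    frequency and log-odds matrices, distance-restraint export, and a seeded
    synthetic-spectra generator with ground-truth manifests for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
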