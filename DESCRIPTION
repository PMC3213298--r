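Package: homint
Title: Homology-Based Prediction of Protein-Protein Interface Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-homology transfer of protein-protein interface
    annotations. Implements a non-partner-specific (NPS) and a
    partner-specific (PS) interface residue predictor: BLASTP tabular
    parsing and alignment statistics, Safe/Twilight/Dark homology zones,
    linear interface-conservation models for template ranking, derivation
    of gold-standard interface labels from multi-chain structures
    (Shrake-Rupley solvent accessibility and 4 Angstrom atomic contacts),
    per-position majority voting, protein- and residue-based evaluation
    metrics, and a synthetic complex/homolog generator for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
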