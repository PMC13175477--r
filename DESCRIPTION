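Package: spryscreen
Title: Length-Calibrated Interface Scoring of Predicted Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate protein-protein interactions from
    AlphaFold-style complex predictions. Reads predicted aligned error
    (PAE) matrices in the common JSON dialects together with predicted
    structures (PDB/mmCIF), computes an interaction score as the grand
    sum of reversed PAE over the inter-chain blocks (observed contacts)
    normalized by a length-calibrated expectation (expected contacts),
    and classifies high-confidence pairs against a fixed cutoff.
    Residue-level tools extract and classify inter-chain contacts
    (generic, polar, salt bridge) and map them onto domain annotations;
    profile analytics compare binding profiles across baits (Pearson and
    Spearman correlations, sequence-identity relationships, full-length
    versus SPRY-only concordance); a chimera builder concatenates
    domain-swap constructs with per-residue provenance. A synthetic
    fixture generator with closed-form ground truth supports testing
    without structure-prediction runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
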