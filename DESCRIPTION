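Package: proteact
Title: Protease Activity Inference from Urinary Peptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers changes in protease activity between two clinical groups
    from naturally occurring urinary peptides. Implements the full chain:
    differential peptide abundance testing (Mann-Whitney with
    Benjamini-Hochberg false discovery rate control and fold-change gates),
    cleavage-site based assignment of candidate proteases to regulated
    peptides from their termini and a curated cleavage-site table, a
    per-protease activity score built from the imbalance of up- versus
    down-regulated associated peptides, and annotation of each scored
    protease against external transcript- and protein-level direction
    evidence. A seeded synthetic-cohort generator makes every stage testable
    end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
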