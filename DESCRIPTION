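Package: ighvg4
Title: Strand-Resolved G-Quadruplex Potential Analysis of Immunoglobulin
    Heavy-Chain V Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing G-quadruplex (G4) formation potential in
    immunoglobulin heavy-chain variable (IGHV) germline genes and its
    relationship to somatic hypermutation. Provides IMGT-gapped sequence
    handling, a deterministic canonical-motif G4 scorer behind a pluggable
    scorer contract, integrated-gradients attribution, strand-resolved
    in-silico saturation mutagenesis with AID hotspot/coldspot
    classification, percent-mismatch (G4-seq style) track handling with
    observed-G4 calling, AID motif density and region activity statistics,
    repertoire mutability analyses, and synthetic-data generators that
    emulate each external input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
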