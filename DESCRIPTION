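Package: rnasefam
Title: Evolutionary Analysis of the Mammalian RNase A Multigene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the birth-death evolution and functional
    diversification of multigene families, built around the mammalian
    ribonuclease (RNase) A superfamily. Provides gene/pseudogene
    classification of intronless coding sequences, protein-guided codon
    alignment with complete-deletion site filtering, pairwise evolutionary
    distances (p-distance, Kimura 2-parameter) and modified Nei-Gojobori
    dN/dS estimation with bootstrap standard errors, neighbor-joining tree
    reconstruction with bootstrap supports, ortholog/paralog selection
    summaries, gene-tree/species-tree reconciliation and Dollo minimum-loss
    counting, isoelectric-point and charged-residue profiling, and a
    seeded gene-family simulator that emits sequences together with a
    ground-truth event log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
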