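Package: ugtfam
Title: Phylogenomics of Conserved-Motif Gene Families: Mining, Intron
    Evolution and Digital Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide analysis of plant
    multigene families characterized by a conserved signature motif, such
    as the family-1 UDP glycosyltransferases (UGTs) and their 44-residue
    PSPG box.  Mines candidate family members from an annotated genome by
    ungapped motif scanning, applies length and intron-count filters,
    detects duplicated, orthologous and lineage-diverged genes, builds a
    neighbour-joining phylogeny with bootstrap supports and reference-based
    group assignment, maps intron positions and phases onto the family
    alignment, clusters them into conserved intron classes and infers
    gain/loss events by Dollo parsimony, and profiles digital expression
    from EST counts, microarray-style log2 matrices and qPCR delta-CT
    tables.  Ships a synthetic-data generator that evolves a gene family
    along a known tree with a planted motif, intron history and expression
    weights, so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    data.table,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
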