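Package: bifcscan
Title: Sort-Seq Deep Mutational Scanning of Receptor Self-Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scans of membrane receptor
    self-association read out by bimolecular fluorescence complementation
    (BiFC) and fluorescence-activated cell sorting. Provides a ground-truthed
    sort-seq simulator for single-site saturation mutagenesis libraries
    (FACS expression and top-fraction BiFC gates, multinomial read sampling,
    FASTQ emission), codon-level variant counting against a reference coding
    sequence, wild-type-normalized log2 enrichment ratios with naive-library
    frequency filters, per-residue conservation scores, replicate-concordance
    diagnostics, aggregation-mutant prediction and population-variant
    cross-referencing, and projection of conservation scores onto protein
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
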