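Package: niltr
Title: Genomic Characterisation of Novel Immunoglobulin-Like Transcript
    (NILT) Receptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotation and comparative analysis of clustered
    immunoglobulin-like innate-immune receptor (NILT) gene families from
    genomic loci. Assembles exon-level annotations into gene models,
    computes exon/intron structure tables and intron phases, detects
    pseudogenes (internal stops, frameshifts, missing exons, non-canonical
    splice sites), and annotates receptor features: V-type Ig-domain
    cysteine spacing classes (CXnC), ITIM signalling motifs, Ser/Thr-rich
    connecting peptides, transmembrane charge, and diagnostic-residue
    group calls. Includes pairwise identity/similarity matrices, a
    progressive multiple aligner, per-column Shannon-entropy variability
    profiles, neighbour-joining trees with bootstrap support, a
    clone-repertoire dedup/singleton survey, and a ground-truthed
    synthetic locus and clone-library simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
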