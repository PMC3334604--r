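Package: smORFpipe
Title: Comparative Discovery of Conserved Small Open Reading Frames
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a comparative
    smORF (small open reading frame) discovery pipeline for pairs of related
    genomes. Candidate single-exon ORFs of 30-300 bp are extracted from
    non-exonic DNA and passed through a cascade of filters: nucleotide
    similarity exclusion against coding/transposon databases, seeded
    translated (six-frame) homology search with Karlin-Altschul E-values,
    conserved-ORF-structure calling by flank re-alignment, synteny against
    ortholog anchors, Nei-Gojobori Ka/Ks with empirical FDR-calibrated
    thresholds, and strand-aware multiple-evidence-of-transcription rules.
    A synthetic genome-pair generator with planted ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
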