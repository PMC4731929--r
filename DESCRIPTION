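Package: aluexon
Title: Proteotranscriptomic Assessment of Protein-Coding Alu Exons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies Alu-derived internal exons in gene models, classifies
    their coding region and nonsense-mediated-decay (NMD) fate on
    reconstructed exon-inclusion transcripts, quantifies exon inclusion
    (percent-spliced-in) from splice-junction read counts in RNA-seq and
    ribosome-profiling data, maps peptide libraries onto inclusion-isoform
    open reading frames with a negative-control false-discovery-rate
    estimate, and calls common versus isoform-specific differential A-to-I
    RNA editing from replicated edited/unedited count tables. A synthetic
    data generator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
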