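Package: apescan
Title: Genome Scanning for A-Form DNA Promoter Elements by Trinucleotide
    Propensity Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts A-form DNA promoter elements from genomic sequence by
    per-base A-DNA propensity energy (APE) scoring with a trinucleotide
    energy table summed over both strands. Detects runs of consecutive
    negative APE values (A-form promoter sequences, APS), couples them to
    nearby direct read-out promoter motifs to form combined promoter
    sequences (CPS) in regions upstream of transcription start sites, and
    quantifies enrichment against a Monte-Carlo base-composition null.
    Reads FASTA genomes and GFF3 gene annotations, and writes results as
    tab-separated tables and BED/WIG/GFF3 genome-browser tracks. Includes
    a synthetic genome generator with planted elements for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
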