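Package: txqc
Title: Quality Control and Refinement of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control and refinement of transcript
    collections from non-model organisms with GC-rich genomes and
    non-canonical splicing. Implements stop-to-stop and Met-to-stop open
    reading frame extraction, rule-based splitting of artificially fused
    transcripts, gold-standard presence checking at the DNA and protein
    level with a match-based local alignment hit score, splice-junction
    extraction and donor/acceptor classification (including the
    non-canonical GC-AG class), detection of unexplained transcribed
    regions from per-base coverage, intron-retention assessment, greedy
    identity-based redundancy removal, containment-aware merging of
    transcript collections, and a deterministic synthetic-fixture
    generator that plants known junction mixes, fusions, retention rates
    and coverage islands for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
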