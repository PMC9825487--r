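Package: uorfkit
Title: Identification and Annotation of Upstream Open Reading Frames from
    Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates candidate upstream open reading frames (uORFs) in
    mRNA 5'UTRs from genome sequence and GTF annotation, classifies them
    (non-overlapping, out-of-frame overlapping, N-terminal extension),
    annotates Kozak context strength and peptides, ingests ribosome
    profiling alignments into P-site profiles with length-dependent offset
    calibration, applies library-level quality gates (read length
    distribution, reading-frame enrichment, library size), calls actively
    translated uORFs from 3-nt periodicity and read uniformity, selects
    representative uORFs among shared-stop groups, and classifies the
    effects of 5'UTR variants (VCF) on uORF structure. Includes a
    synthetic-data generator producing transcriptomes, ribosome-protected
    fragment libraries and variant sets with known ground truth, and a
    one-command pipeline with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
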