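Package: flcdna
Title: Characterization of Full-Length cDNA Libraries by Comparative
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing single-pass full-length cDNA (EST)
    collections against an annotated reference transcriptome and genome:
    quality/vector/host cleaning, affine-gap local alignment with best-hit
    selection, classification of aligned spans into UTR/CDS mapping
    categories, per-gene consensus building with per-region identity
    statistics, triage of transcripts without a reference homolog by
    database evidence, spliced genome mapping and ORF content, INDEL
    detection with region classification, and screening for transposable
    element derived (exonized) cassette exons.  Includes a synthetic-data
    generator that emulates a directional oligo-capped placenta cDNA
    library with a full ground-truth ledger, used throughout the test
    suite for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
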