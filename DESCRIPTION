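Package: smrclust
Title: Annotation-Free Discovery and Quantification of Small RNA Read Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small RNA read clusters (smRCs) genome-wide from aligned
    small RNA-seq reads without relying on genome annotation. Implements
    adapter trimming with a 5' head trim and 3' homopolymer adapter removal,
    fractional redistribution of multi-mapping reads in proportion to the
    unique-read coverage at each candidate site, gap-based cluster calling
    with a minimum inter-cluster distance and minimum read-count threshold,
    per-cluster characterization metrics (coverage-entropy complexity, peak
    coverage and peak fraction, majority-vote consensus sequence), biotype
    annotation against a reference gene model, and construction of a
    cross-sample count matrix with CPM/RPKM normalization and expression
    filtering. Includes a seeded simulator that plants clusters with known
    shapes, multi-mapping decoy loci, and background reads for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
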