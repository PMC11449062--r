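Package: camevo
Title: Comparative Genomics of CAM Evolution in Paired Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream comparative-genomics pipeline linking the evolution of
    Crassulacean acid metabolism (CAM) to gene family expansion, diel expression
    divergence, coding-sequence evolution, circadian cis-element composition and
    transposable-element insertion patterns between two congeneric genomes. Provides
    coverage-based correction of orthogroup gene counts, a two-stage polynomial
    regression caller for differential diurnal expression, pairwise dN/dS estimation
    under a Goldman-Yang codon model with a likelihood-ratio test against neutrality,
    promoter scanning for circadian motifs, TE-gene intersection statistics, windowed
    genome-composition statistics, diel metabolite statistics, and a fully seeded
    synthetic-data generator that plants recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
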