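Package: screenmap
Title: Pooled Homozygosity Mapping and Expression Screening for Forward
    Genetic Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identification of recessive point mutations from pooled
    whole-exome variant calls of an F2 incross (bulked segregant
    analysis), as used in zebrafish forward genetic screens. Implements
    windowed mutant-specific homozygosity scoring with peak detection,
    screening of the mapped interval for nonsense and essential splice
    variants, intron-retention premature-stop-codon prediction,
    duplication-aware FPKM quantification with pure fold-change
    differential expression, a thresholded novel/differential
    splice-junction screen, and ddCt qPCR relative quantification.
    Seeded simulators for the F2 cross, RNA-seq counts with planted
    effects, and qPCR Ct tables make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
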