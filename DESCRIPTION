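Package: gadarch
Title: Genome Architecture of Codfish-Like Assemblies: Tandem Repeats and
    Multi-Copy Immune Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perfect short tandem repeats (unit size 1-10 bp) in
    genome assemblies, computes density and frequency statistics genome-wide
    and within coding sequence, tests Gene Ontology level enrichment of
    STR-carrying genes within and between species with Fisher's exact test
    and Benjamini-Yekutieli false discovery rate control, censuses
    multi-copy immune-gene domains (NLR- and MHC class I-style) by six-frame
    translation and ungapped profile scanning with fractional-length
    thresholds, and diagnoses assembly-collapsed gene copies from normalized
    read depth. Ships a synthetic-genome simulator with planted ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
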