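Package: enhancerSNV
Title: Non-Coding Somatic SNVs in Tumor-Type-Specific Enhancer Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for interpreting non-coding somatic
    single-nucleotide variants (SNVs) that fall in tumor-type-specific
    enhancer elements. From two cohorts of per-sample chromatin
    accessibility peak sets it calls group-specific and shared accessible
    regions, classifies them against promoter/insulator/enhancer
    annotation tracks with a chi-square enrichment test, intersects
    per-patient somatic SNVs with group-specific enhancers, clusters
    mutational hotspots and prioritizes candidate enhancers, scores
    wild-type versus mutant sequence windows against a position weight
    matrix library to detect gained, lost and novel transcription factor
    binding sites, and summarizes targeted-sequencing validation cohorts
    (callability, mutation frequency, co-occurrence, multifocal
    concordance, peritumoral exclusivity). A synthetic-data module
    generates every input with machine-readable planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
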