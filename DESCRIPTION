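Package: imprintscan
Title: Mono- Versus Bi-Allelic Expression at Imprinted Loci from RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects loss of genomic imprinting from bulk RNA-seq by scoring
    bi-allelic expression of imprinted genes and their locus neighbours.
    Parses samtools mpileup text, calls SNPs with VarScan-style thresholds
    (minimum average base quality, variant allele frequency, variant-supporting
    reads) plus a per-site depth post-filter, summarises each transcript by its
    bi-allelic SNP frequency per kilobase, and tests imprinting-status by
    pig-group effects with ANOVA (sex covariate) and Tukey HSD contrasts.
    Includes a seeded allele-specific read-pileup simulator that emulates a
    three-group cohort over a panel of imprinted loci and 2 Mb neighbour genes,
    so the full analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    car,
    yaml,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
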