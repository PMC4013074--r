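Package: nilscan
Title: Cryptic Introgression and De Novo Mutation Analysis for Nearly-Isogenic Lines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome and transcriptome comparison of nearly-isogenic plant
    lines against a reference background. Filters paired whole-genome
    variant calls to line-discriminating SNPs (homozygous-divergent sites
    passing depth, site-quality and genotype-quality thresholds), localizes
    cryptic introgression intervals by a windowed SNP-density scan with
    gap-tolerant merging, classifies private SNPs against a haplotype panel
    into standing (introgressed) versus de novo variation, characterizes
    the strand-collapsed substitution spectrum, estimates generational
    distance from de novo mutation counts, checks genotype concordance
    between whole-genome and RNA-seq replicate calls, and summarizes
    differentially expressed genes relative to the introgression intervals.
    Includes a fully parameterized synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
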