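#!/usr/bin/env Rscript
# Generate the synthetic nearly-isogenic-line experiment used by the rest
# of the analysis: paired WGS VCF, replicated RNA-seq VCF, haplotype
# panel, exon annotation, DE-gene table and ground truth.
suppressMessages(library(nilscan))

outdir <- "results/sim"
cfg <- sim_config(seed = 1)
sim <- simulate_nil(cfg, outdir = outdir)

truth <- sim$truth$snps
message(sprintf("simulated %d SNP sites on a %d-chromosome, %.0f Mb genome:",
                nrow(truth), nrow(cfg$layout), genome_size(cfg$layout) / 1e6))
message(sprintf("  %d introgression (3 blocks, %.1f Mb combined), %d + %d de novo, %d background",
                sum(truth$label == "introgression"),
                sum(sim$truth$blocks$end - sim$truth$blocks$start) / 1e6,
                sum(truth$label == "denovo_a"), sum(truth$label == "denovo_b"),
                sum(truth$label == "background")))
message("bundle written under ", outdir)
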