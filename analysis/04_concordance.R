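#!/usr/bin/env Rscript
# Genotype the RNA-seq replicates at the WGS-discovered SNP positions,
# measure concordance, re-discover group-discriminating SNPs without
# using the WGS positions, and scan per-bin heterozygosity.
suppressMessages(library(nilscan))

layout <- read_genome_layout("results/sim/layout.tsv")
rna <- read_vcf("results/sim/rna.vcf")
snps <- utils::read.table("results/discriminating_snps.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
targets <- snps[snps$private_to == "B", ]
grp_a <- grep("^A", rna$samples, value = TRUE)
grp_b <- grep("^B", rna$samples, value = TRUE)

calls <- genotype_at_sites(rna, targets, min_depth = 10)
rep_b <- concordance_report(calls[, grp_b, drop = FALSE], targets,
                            expected = "hom_alt")
rep_a <- concordance_report(calls[, grp_a, drop = FALSE], targets,
                            expected = "hom_ref")
message(sprintf(
  "group B: %d typed, %d (%d%%) non-reference, %d reference, %d het",
  rep_b$n_typed, rep_b$n_match_expected, rep_b$pct_match,
  rep_b$n_other_allele, rep_b$n_het))
message(sprintf("group A: %d typed, %d%% reference as expected",
                rep_a$n_typed, rep_a$pct_match))

disc <- group_discriminating(rna, grp_a, grp_b)
grid <- bin_snp_counts(disc, layout)
utils::write.table(grid, "results/rna_bin_counts_100kb.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d group-discriminating SNPs found from RNA-seq alone",
                nrow(disc)))

hs <- het_scan(rna, layout)
message(sprintf("%d bin(s) flagged for elevated heterozygosity",
                nrow(hs$flagged)))
write_report(list(group_b = rep_b[c("n_typed", "n_match_expected",
                                    "n_other_allele", "n_het", "pct_match")],
                  group_a = rep_a[c("n_typed", "pct_match")],
                  n_group_discriminating = nrow(disc),
                  het_flagged_bins = hs$flagged),
             "results/concordance.json")
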