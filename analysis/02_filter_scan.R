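#!/usr/bin/env Rscript
# Filter the paired WGS calls to line-discriminating SNPs and scan their
# density in 100 kb bins to delineate introgression intervals.
suppressMessages(library(nilscan))

layout <- read_genome_layout("results/sim/layout.tsv")
wgs <- read_vcf("results/sim/wgs.vcf")
priv <- classify_private(wgs, "A", "B")
message(sprintf("retained %d of %d sites; private to A: %d, to B: %d",
                priv$n_retained, priv$n_input,
                priv$counts[["A"]], priv$counts[["B"]]))

utils::write.table(priv$snps, "results/discriminating_snps.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

snps_b <- priv$snps[priv$snps$private_to == "B", ]
grid <- bin_snp_counts(snps_b, layout)
utils::write.table(grid, "results/bin_counts_100kb.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

intervals <- call_intervals(grid)
met <- interval_metrics(intervals, layout, total_snps = nrow(snps_b))
write_intervals_bed(intervals, "results/introgression_intervals.bed", layout)
write_report(list(intervals = met$per_interval,
                  combined_mb = met$combined_mb,
                  pct_of_genome = met$pct_of_genome,
                  genetic_length_cm = met$genetic_length_cm),
             "results/scan.json")

message(sprintf("%d interval(s): %s", nrow(intervals),
                paste(met$per_interval$label, collapse = "; ")))
message(sprintf("combined %.1f Mb = %.1f%% of the genome, ~%.1f cM",
                met$combined_mb, met$pct_of_genome, met$genetic_length_cm))
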