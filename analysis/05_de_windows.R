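#!/usr/bin/env Rscript
# Threshold the differential-expression table (q <= 0.05, |log2 FC| >= 2),
# count DE genes in 10 Mb windows, and relate them to the introgression
# intervals.
suppressMessages(library(nilscan))

layout <- read_genome_layout("results/sim/layout.tsv")
de_tab <- read_de_table("results/sim/de_genes.tsv")
intervals <- read_intervals_bed("results/introgression_intervals.bed")

de_set <- filter_de(de_tab)
ov <- de_interval_overlap(de_set, intervals)
wins <- de_window_counts(de_set, layout, width = 1e7)
utils::write.table(wins, "results/de_window_counts_10mb.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_report(list(n_input = nrow(de_tab), n_de = nrow(de_set),
                  n_in_intervals = ov$n_inside,
                  n_outside = ov$n_outside),
             "results/de.json")
message(sprintf(
  "%d of %d genes pass the DE thresholds; %d inside the introgression intervals, %d outside",
  nrow(de_set), nrow(de_tab), ov$n_inside, ov$n_outside))
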