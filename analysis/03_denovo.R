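#!/usr/bin/env Rscript
# Classify each line's private SNPs against the haplotype panel, derive
# the de novo sets, characterize the substitution spectrum, and estimate
# the generational distance between the lines and the reference.
suppressMessages(library(nilscan))

snps <- utils::read.table("results/discriminating_snps.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
panel <- read_panel("results/sim/panel.tsv")
intervals <- read_intervals_bed("results/introgression_intervals.bed")
layout <- read_genome_layout("results/sim/layout.tsv")
# rate model over the genome actually analyzed
model <- mutation_rate_model(7e-9, genome_size(layout))

by_line <- split(snps, snps$private_to)
out <- list()
for (line in names(by_line)) {
  s <- by_line[[line]]
  pm <- panel_membership(s, panel)
  dn <- derive_denovo(s, panel, intervals)
  sp <- mutation_spectrum(dn)
  gens <- generations_removed(nrow(dn), model)
  out[[line]] <- list(n_private = nrow(s),
                      panel_fraction_pct = pm$fraction_pct,
                      n_denovo = nrow(dn),
                      spectrum = as.list(sp),
                      generations_removed = gens)
  message(sprintf(
    "line %s: %d private SNPs, %.1f%% in panel; %d de novo -> ~%d generations (top class %s)",
    line, nrow(s), pm$fraction_pct, nrow(dn), gens, names(which.max(sp))))
}
out$model <- list(mu = model$mu, genome_bp = model$genome_bp,
                  mutations_per_generation = mutations_per_generation(model))
write_report(out, "results/denovo.json")
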