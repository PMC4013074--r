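# nilscan

Purity QC and cryptic-introgression mapping for nearly-isogenic plant
lines from paired resequencing data.

Seed stocks of "identical" inbred lines drift apart: an unnoticed
outcross leaves small fixed blocks of foreign genotype (cryptic
introgressions), and ordinary propagation adds a handful of spontaneous
mutations every generation. Both appear as homozygous-divergent SNPs when
two individuals are resequenced against the shared reference, but they
separate cleanly by *clustering* and by *haplotype-panel membership*.
`nilscan` implements that separation as a tested pipeline for anyone who
maintains, distributes, or fine-maps with inbred germplasm:

1. **Filter** paired variant calls to line-discriminating SNPs: depth
   ≥ 10 in both samples, site quality ≥ 40, both genotypes homozygous
   (GQ ≥ 10) and different. Each retained SNP is private to the line
   carrying the non-reference allele.
2. **Scan** private-SNP density in non-overlapping 100 kb bins; bins with
   > 2 SNPs, merged across gaps of ≤ 5 bins, become introgression
   intervals with physical span, % of genome, genetic length
   (span × 3 cM/Mb), and per-interval SNP shares.
3. **Classify** private SNPs against a haplotype panel: members are
   standing (introgressed) variation; non-members outside the intervals
   are de novo mutations. The strand-collapsed 6-class substitution
   spectrum and the generation distance
   `round(n / (mu x G))` (defaults mu = 7e-9, G = 2.3 Gbp, i.e. ~16
   mutations/generation) summarize them.
4. **Check** fixation with replicated RNA-seq: genotype the discovered
   positions (≥ 10 reads), tally concordance over sites typed in every
   replicate, re-discover group-discriminating SNPs without the WGS
   positions, and flag high-heterozygosity bins (collapsed paralogs).
5. **Relate** differentially expressed genes (q ≤ 0.05, |log2 FC| ≥ 2) to
   the intervals in 10 Mb windows.

A fully ground-truthed synthetic-data generator (`simulate_nil()`)
produces the complete input bundle — paired WGS VCF, replicated RNA-seq
VCF, panel, exon annotation, DE table — so every stage is validated
end-to-end against planted truth.

## Worked example

```r
library(nilscan)
sim    <- simulate_nil(sim_config(seed = 1), outdir = "results/sim")
report <- run_pipeline(sim$paths)
```

which logs:

```
[filter] 4686 sites read, 4186 retained (A: 31, B: 4155)
[scan] 3 interval(s), combined 4.6 Mb
[classify] de novo 30/73; ~16 mutations/generation
[annotate] 232/4186 SNPs exonic (5.5%)
[concord] 386 typed in group B, 100% matching WGS
[dewindows] 121 DE genes, 10 in intervals
```

Reading: of 4,686 input sites the filter keeps 4,186 discriminating SNPs
(the 500 planted noise sites all fail); the density scan recovers the
three planted blocks exactly (`chr1 14.0–15.1`, `chr5 8.1–8.6`,
`chr10 12.3–15.3 Mb`, combined 4.6 Mb = 2.3% of the 200 Mb desk genome);
30 and 73 SNPs classify as de novo after panel and interval exclusion;
all RNA-typed sites agree with the WGS genotypes; and 121 genes pass the
DE thresholds, 10 overlapping the intervals. The numbered scripts under
`analysis/` run the same stages one at a time and write every table under
`results/`.

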