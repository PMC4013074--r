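---
title: "Detecting cryptic introgressions and de novo mutations in nearly-isogenic lines"
author: "nilscan"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilscan)
```

## The problem

Inbred plant lines maintained at different institutions are assumed to be
genetically identical, but seed stocks can silently diverge: an unnoticed
cross followed by backcrossing and selfing leaves small, fixed segments of
foreign genotype — *cryptic introgressions* — embedded in an otherwise pure
background, while ordinary propagation accumulates sparse spontaneous
mutations genome-wide. Both classes of variant surface as homozygous
differences when two supposedly identical individuals are resequenced
against the common reference, but they differ sharply in two measurable
ways: introgressed SNPs are *clustered* (hundreds per 100 kb inside the
segment) and are mostly *standing variation* catalogued in haplotype
panels, whereas de novo mutations are *uniformly scattered* and almost
never panel members. `nilscan` turns those two signatures into a pipeline:
filter paired variant calls to line-discriminating SNPs, localize
introgressions by windowed SNP density, classify the remainder against a
haplotype panel, characterize the mutation spectrum, and estimate how many
propagation cycles separate the genomes.

## The discriminating-SNP filter

The unit of analysis is a biallelic SNP with per-sample genotype, read
depth and genotype quality, plus a per-site quality score. A site is
retained when

* both samples have depth ≥ 10,
* site quality ≥ 40,
* both genotypes are homozygous (reference or alternative) with genotype
  quality ≥ 10, and
* the two genotypes differ.

Heterozygous and missing calls always fail, however confident: a
homozygous inbred comparison has no legitimate het class, and hets mostly
flag collapsed paralogs. Records that are half-missing fail the depth or
genotype check by construction. Each retained SNP is *private to* the line
carrying the non-reference allele, and the two private sets partition the
retained total. Missing DP/GQ fields are read as 0 so that incomplete
records are rejected rather than silently passed.

## The density scan

Private SNPs are counted in non-overlapping 100 kb bins (bin $i$ covers
$[i\,w, (i+1)\,w)$ in 0-based coordinates). Bins with **more than**
`min_snps_per_bin` SNPs (default 2) qualify; qualifying bins on one
chromosome separated by at most `max_gap_bins` (default 5) sub-threshold
bins merge into one interval whose bounds are the outermost qualifying
bins' edges. Bounds are therefore bin-aligned, which is why interval
coordinates render losslessly as Mb to one decimal. The gap tolerance
exists because a real introgressed segment contains interior bins that
happen to fall below threshold; merging across short gaps recovers one
contiguous interval rather than a fragmented set, and raising the
tolerance can only reduce the interval count (never increase it). An
interval's `snp_count` sums *all* its bins, gap bins included.

Physical metrics follow directly: combined span, fraction of the genome,
and genetic length as span (Mb) × `cm_per_mb` (default 3 cM/Mb, a typical
subtelomeric recombination rate). Per-interval SNP shares are reported
against the line's complete private-SNP count. All reported decimals are
rounded half away from zero to one decimal; headline concordance
percentages are integer-rounded.

## Panel classification and de novo mutations

Private SNPs are intersected with a haplotype panel by exact position
(allele-aware matching is an opt-in strictness flag; position-only is the
default because panel genotype files are position-indexed and
tabix-style lookups are positional). A high member fraction marks a
private set as standing variation — an introgression from another
genotype — while a near-zero fraction marks read-mapping artifacts plus
genuine spontaneous mutations.

The **de novo set** is defined as: private to one line, absent from the
panel, and (by default) outside the called introgression intervals. The
interval exclusion matters: inside an introgressed segment, a
non-panel SNP is far more likely to be uncatalogued donor variation than
a new mutation. Both definitions (`exclude_intervals = TRUE`/`FALSE`) are
supported and reported.

Each de novo SNP maps to one of six strand-collapsed substitution classes
(G:C→A:T, A:T→G:C, G:C→T:A, G:C→C:G, A:T→T:A, A:T→C:G); complementing
both alleles never changes the class, and class counts conserve the input
size. In plants the spectrum is expected to be transition-biased with
G:C→A:T heaviest, consistent with spontaneous deamination of methylated
cytosines.

With a base-substitution rate $\mu$ per site per generation (default
$7\times10^{-9}$, the *Arabidopsis thaliana* estimate used as a proxy)
and genome size $G$ (default 2.3 Gbp), the expected number of mutations
per propagation cycle is $\mu G \approx 16$, and a de novo count $n$
translates into $\hat g = \mathrm{round}(n/(\mu G))$ generations of
separation. The quotient is rounded on the final value, computed from the
unrounded per-generation rate. The estimator inherits Poisson noise, so
$\hat g$ recovers a simulated $g$ only to within a few generations
($\pm 3\sqrt{g/16}$ covers essentially all replicates).

## RNA-seq concordance and group discovery

Replicated RNA-seq samples provide an independent check that an
introgression is fixed in all individuals of a line. Genotypes are called
at the WGS-discovered positions only where at least 10 reads are present;
a site is *typed* for a group when every replicate yields a call and the
calls are unanimous. Typed sites are classified by their consensus
against the expected genotype; sites called in all replicates but
disagreeing among them are listed separately as replicate-discordant
rather than folded into any tally, so `typed = match + other + het`
always holds. A fallback caller from allele depths (homozygous at major
fraction ≥ 0.9, het at minor fraction ≥ 0.2, otherwise missing) supports
inputs without genotype fields; its thresholds are conventional hard
cutoffs, configurable, and deliberately leave an ambiguous zone that maps
to missing.

Independently of the WGS positions, group-discriminating SNPs are
re-discovered from the RNA-seq samples alone: sites where every replicate
of one line is homozygous for one allele and every replicate of the other
line homozygous for the other, all passing the same depth/quality
thresholds. With one sample per group this reduces exactly to the
two-sample filter (a tested cross-module identity). A per-bin
heterozygosity scan (flagging bins with > 20 hets in at least one sample
and ≥ 14 in all) exposes collapsed paralogous regions and residual
heterozygosity.

## DE genes relative to the intervals

The differential-expression table is an input (testing happens upstream);
`nilscan` thresholds it at corrected $q \le 0.05$ and $|\log_2 FC| \ge 2$.
The fold-change cut is applied to the absolute value because genes move
in both directions; when the column is absent the ratio is computed from
the group FPKM means with a $10^{-3}$ pseudo-expression. DE genes are
counted in 10 Mb windows by locus start (so a boundary-spanning gene
counts once and totals conserve) and partitioned by any-overlap against
the introgression intervals — the biologically loaded contrast, since
*trans*-acting variation inside an introgression can move transcripts
anywhere in the genome.

## What the simulator emulates — and what it does not

The generator plants, on a 10 × 20 Mb genome:

* three introgression blocks (1.1, 0.5 and 3.0 Mb; combined 4.6 Mb) at
  9 × 10⁻⁴ SNPs/bp, the density regime of a real introgressed segment
  (~0.9 SNPs/kb, hundreds per 100 kb bin);
* 31 and 77 de novo SNPs in lines A and B — full-genome-scale
  densities (358 and 883 per 2.3 Gbp) preserved *per bp* at desk scale,
  so over-threshold background bins are essentially absent and the scan's
  specificity is actually exercised;
* de novo alleles drawn from a transition-biased spectrum
  (0.50, 0.20, 0.10, 0.08, 0.07, 0.05 over the six classes);
* panel membership at 0.75 for introgressed and 0.05 for de novo SNPs,
  plus 3,000 decoy panel positions;
* 500 background sites, each constructed to violate at least one
  retention criterion (low depth, low site quality, a het call, low
  genotype quality, or concordant genotypes), so filter correctness is
  directly assertable;
* negative-binomial depth (mean 30, size 8), floored at 10 for planted
  sites so that the depth filter binds only on background noise;
* a 10% transcribed subset genotyped in 3 + 3 replicates with independent
  depths and an optional per-call error rate (default 0);
* a 1,000-gene DE table with 121 genes passing both thresholds, nine of
  them placed inside the blocks.

The bundle is a deterministic, byte-identical function of the seed, and
every SNP carries a ground-truth label, which is the oracle for the
end-to-end tests. A full default run finishes in a few seconds on one
CPU; the problem sizes above (200 Mb genome, ~4,700 sites, 100-replicate
recovery loops) were chosen so that the complete suite runs in well under
a minute while keeping every density regime of the real analysis.

What it does **not** model: read-level errors and alignment (inputs are
genotype calls, not reads), linkage structure within the donor haplotype,
copy-number or presence/absence variation, position-dependent depth
(GC/mappability), or residual-heterozygosity blocks. Passing tests
therefore validate the *computation* — filtering, scanning, classifying,
estimating — under the stated statistical structure, not the upstream
calling pipeline.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally; VCF positions convert on
read and reports render Mb to one decimal (lossless for bin-aligned
bounds). Multi-allelic and indel records are dropped at read time with
counts; duplicate positions keep the first record with a warning. An
empty SNP set yields `NA` fractions (JSON `null`), an empty interval set
a header-only BED that round-trips to an empty set. Overlapping intervals
passed to the metrics stage are an assembly bug and fail loudly.
Percentages round half away from zero; tables produced by truncation
instead can differ by 0.1 in the last digit, a rendering — not a
counting — difference.

## A worked desk-scale run

```{r, eval = FALSE}
sim <- simulate_nil(sim_config(seed = 1), outdir = "results/sim")
report <- run_pipeline(sim$paths)
report$scan$intervals
report$denovo$generations
```

The numbered scripts under `analysis/` run the same stages step by step
and leave all tables under `results/`; `scripts/acceptance.R` recomputes
the headline quantities (interval metrics, panel fractions, generation
estimates, concordance) from scratch and writes them as JSON.
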