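# In-code fixtures and independent brute-force oracles.

GT4 <- c("hom_ref", "het", "hom_alt", "missing")

# build a site_table directly from per-sample call vectors
make_table <- function(chrom, pos, ref = "A", alt = "G", qual = 100,
                       samples = c("A", "B"), gt, dp = 30, gq = 60) {
  n <- length(pos)
  expand <- function(x) {
    m <- matrix(x, nrow = n, ncol = length(samples))
    colnames(m) <- samples
    m
  }
  site_table(
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               qual = rep_len(qual, n), stringsAsFactors = FALSE),
    samples, gt = expand(gt), dp = expand(dp), gq = expand(gq))
}

# independent per-site re-implementation of the retention rule, written as
# plain conditionals (the oracle for site_passes / classify_private)
brute_force_pass <- function(qual, ga, gb, da, db, qa, qb,
                             min_dp = 10, min_qual = 40, min_gq = 10) {
  if (da < min_dp) return(FALSE)
  if (db < min_dp) return(FALSE)
  if (qual < min_qual) return(FALSE)
  if (!(ga == "hom_ref" || ga == "hom_alt")) return(FALSE)
  if (!(gb == "hom_ref" || gb == "hom_alt")) return(FALSE)
  if (qa < min_gq) return(FALSE)
  if (qb < min_gq) return(FALSE)
  ga != gb
}

# naive all-pairs point-in-interval containment (oracle for overlap code)
brute_force_inside <- function(snps, intervals) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(intervals$chrom == snps$chrom[i] &
          intervals$start <= snps$pos[i] &
          snps$pos[i] < intervals$end)
  }, logical(1))
}

# write a small VCF from literal body lines
write_mini_vcf <- function(body, samples = c("A", "B"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
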