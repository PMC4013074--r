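test_that("bin counting handles boundaries and conserves totals", {
  lay <- genome_layout("chr1", 1e6)
  snps <- data.frame(chrom = "chr1", pos = c(0, 99999, 100000))
  g <- bin_snp_counts(snps, lay, width = 100000)
  expect_equal(g$count[1:2], c(2L, 1L))
  expect_equal(sum(g$count), 3L)

  g0 <- bin_snp_counts(snps[0, ], lay)
  expect_true(all(g0$count == 0))
  expect_error(bin_snp_counts(data.frame(chrom = "chr1", pos = 1e6), lay),
               "outside")
})

test_that("bin counts match a brute-force histogram on uniform SNPs", {
  set.seed(21)
  lay <- genome_layout("chr1", 1e7)
  pos <- sort(sample.int(1e7, 1000)) - 1
  g <- bin_snp_counts(data.frame(chrom = "chr1", pos = pos), lay, 100000)
  oracle <- vapply(0:99, function(b)
    sum(pos >= b * 100000 & pos < (b + 1) * 100000), integer(1))
  expect_equal(g$count, oracle)
  expect_equal(sum(g$count), 1000L)
})

test_that("interval calling merges across short gaps only", {
  lay <- genome_layout("chr1", 2e6)
  mk_grid <- function(counts) {
    snps <- data.frame(chrom = "chr1",
                       pos = rep((seq_along(counts) - 1) * 100000, counts))
    bin_snp_counts(snps, lay, 100000)
  }
  # qualifying bins 3,4,5 (0-based) contiguous -> one interval
  g <- mk_grid(c(0, 0, 0, 5, 4, 6, 0, 0))
  iv <- call_intervals(g, scan_params())
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(300000, 600000))
  expect_equal(iv$snp_count, 15L)
  expect_equal(iv$max_bin_count, 6L)

  # qualifying bins 3 and 10: gap of 6 non-qualifying bins > max_gap 5
  g2 <- mk_grid(c(0, 0, 0, 5, 0, 0, 0, 0, 0, 0, 7))
  iv2 <- call_intervals(g2, scan_params(max_gap_bins = 5))
  expect_equal(nrow(iv2), 2L)
  # with max_gap 6 they merge, and gap bins join the snp_count sum
  iv3 <- call_intervals(g2, scan_params(max_gap_bins = 6))
  expect_equal(nrow(iv3), 1L)
  expect_equal(iv3$snp_count, 12L)
  expect_equal(iv3$bin_count, 8L)
})

test_that("increasing gap tolerance never increases the interval count", {
  set.seed(22)
  lay <- genome_layout("chr1", 5e6)
  snps <- data.frame(chrom = "chr1", pos = sort(sample.int(5e6, 400)) - 1)
  g <- bin_snp_counts(snps, lay, 100000)
  n_prev <- Inf
  for (gap in 0:8) {
    n <- nrow(call_intervals(g, scan_params(min_snps_per_bin = 5,
                                            max_gap_bins = gap)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("interval metrics reproduce physical/genetic arithmetic", {
  lay <- genome_layout(paste0("chr", 1:10),
                       c(301, 238, 232, 242, 218, 169, 177, 175, 157, 150) * 1e6)
  iv <- data.frame(chrom = c("chr1", "chr5", "chr10"),
                   start = c(292.1, 208.1, 142.3) * 1e6,
                   end = c(293.2, 208.6, 145.3) * 1e6,
                   snp_count = c(1103L, 450L, 2809L))
  m <- interval_metrics(iv, lay, scan_params(cm_per_mb = 3), genome_bp = 2.3e9,
                        total_snps = 5257)
  expect_equal(m$combined_mb, 4.6)
  expect_equal(m$pct_of_genome, 0.2)
  expect_equal(m$genetic_length_cm, 13.8)
  expect_equal(m$per_interval$share_pct, c(21.0, 8.6, 53.4))
  expect_equal(m$per_interval$label[3], "chr10: 142.3-145.3 Mb")
  # overlapping intervals indicate an assembly bug
  bad <- data.frame(chrom = "chr1", start = c(0, 5e4), end = c(1e5, 2e5))
  expect_error(interval_metrics(bad, lay), "overlap")
})

test_that("a whole-genome interval has fraction 1 and share 100", {
  lay <- genome_layout("chr1", 2e6)
  iv <- data.frame(chrom = "chr1", start = 0, end = 2e6, snp_count = 50L)
  m <- interval_metrics(iv, lay)
  expect_equal(m$fraction_of_genome, 1)
  expect_equal(m$per_interval$share_pct, 100)
})

test_that("planted blocks are recovered within one bin per side", {
  sim <- simulate_nil(sim_config(seed = 31), outdir = tempfile())
  lay <- sim$truth$config$layout
  truth_b <- sim$truth$snps
  priv_b <- truth_b[truth_b$label %in% c("introgression", "denovo_b"), ]
  iv <- call_intervals(bin_snp_counts(priv_b, lay))
  blocks <- sim$truth$blocks
  expect_equal(nrow(iv), nrow(blocks))
  expect_equal(iv$chrom, blocks$chrom)
  expect_true(all(abs(iv$start - blocks$start) <= 1e5))
  expect_true(all(abs(iv$end - blocks$end) <= 1e5))
  # conservation: intervals cannot hold more SNPs than were binned
  expect_lte(sum(iv$snp_count), nrow(priv_b))
})
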