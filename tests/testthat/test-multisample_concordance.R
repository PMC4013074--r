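test_that("genotyping at target sites enforces the 10-read minimum", {
  st <- make_table("chr1", c(100, 200, 300), samples = "R1",
                   gt = c("hom_alt", "hom_alt", "het"),
                   dp = c(8, 15, 30))
  targets <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400))
  calls <- genotype_at_sites(st, targets, min_depth = 10)
  expect_equal(unname(calls[, 1]),
               c("missing", "hom_alt", "het", "missing"))
  # raising min_depth never increases the number of called sites
  n_called <- vapply(c(5, 10, 20, 40), function(d)
    sum(genotype_at_sites(st, targets, min_depth = d) != "missing"),
    numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("fallback caller genotypes from allele depths", {
  st <- make_table("chr1", c(100, 200, 300), samples = "R1",
                   gt = "missing", dp = 0)
  ad <- list(ref = matrix(c(12, 6, 9), ncol = 1),
             alt = matrix(c(0, 6, 1), ncol = 1))
  calls <- genotype_at_sites(st, st$sites, allele_depths = ad)
  expect_equal(unname(calls[, 1]), c("hom_ref", "het", "hom_ref"))
  # minor fraction between 0.1 and 0.2: neither hom nor het -> missing
  ad2 <- list(ref = matrix(17, 1, 1), alt = matrix(3, 1, 1))
  expect_equal(unname(genotype_at_sites(st, st$sites[1, , drop = FALSE],
                                        allele_depths = ad2)[1, 1]),
               "missing")
})

test_that("concordance tallies typed sites by unanimous consensus", {
  n <- 320
  calls <- matrix("hom_alt", nrow = n, ncol = 3)
  calls[1:5, ] <- "hom_ref"      # reference allele in all replicates
  calls[6, ] <- "het"            # unanimously het (discordant with WGS)
  calls[310:315, 2] <- "missing" # untyped: missing in one replicate
  calls[316:320, 1] <- "hom_ref" # replicate-discordant
  targets <- data.frame(chrom = "chr1", pos = seq_len(n))
  rep <- concordance_report(calls, targets, expected = "hom_alt")
  expect_equal(rep$n_typed, 309L)
  expect_equal(rep$n_match_expected, 303L)
  expect_equal(rep$n_other_allele, 5L)
  expect_equal(rep$n_het, 1L)
  expect_equal(rep$pct_match, 98L)
  expect_equal(rep$n_typed, rep$n_match_expected + rep$n_other_allele + rep$n_het)
  expect_equal(nrow(rep$replicate_discordant), 5L)
  expect_equal(nrow(rep$wgs_discordant), 6L)

  all_missing <- matrix("missing", nrow = 4, ncol = 3)
  rep0 <- concordance_report(all_missing, targets[1:4, , drop = FALSE])
  expect_equal(rep0$n_typed, 0L)
})

test_that("concordance on simulated error-free data is 100%", {
  sim <- simulate_nil(sim_config(seed = 61), outdir = tempfile())
  rna <- read_vcf(sim$paths$rna_vcf)
  truth <- sim$truth$snps
  targets <- truth[truth$label %in% c("introgression", "denovo_b"),
                   c("chrom", "pos")]
  calls <- genotype_at_sites(rna, targets, min_depth = 10)
  rep <- concordance_report(calls[, c("B1", "B2", "B3"), drop = FALSE],
                            targets, expected = "hom_alt")
  expect_gt(rep$n_typed, 0)
  expect_equal(rep$pct_match, 100L)
  expect_equal(rep$n_other_allele + rep$n_het, 0L)
})

test_that("concordance under depth dropout and 1% genotype error stays near 99%", {
  sim <- simulate_nil(sim_config(seed = 62, n_denovo_b = 0, n_denovo_a = 0,
                                 n_background = 0, transcribed_fraction = 0.1,
                                 rna_geno_error = 0.01),
                      outdir = tempfile())
  rna <- read_vcf(sim$paths$rna_vcf)
  truth <- sim$truth$snps
  targets <- truth[truth$label == "introgression", c("chrom", "pos")]
  calls <- genotype_at_sites(rna, targets, min_depth = 10)
  rep <- concordance_report(calls[, c("B1", "B2", "B3"), drop = FALSE],
                            targets, expected = "hom_alt")
  # corrupted calls mostly surface as replicate discordance; concordance
  # among typed sites should sit within 3 binomial s.e. of 99%
  expect_gt(rep$n_typed, 100)
  se <- sqrt(0.99 * 0.01 / rep$n_typed)
  expect_lt(abs(rep$n_match_expected / rep$n_typed - 0.99), 3 * se)
  expect_gt(nrow(rep$replicate_discordant), 0)
})

test_that("group-discriminating sites require fixed opposite homozygotes", {
  samples <- c("A1", "A2", "A3", "B1", "B2", "B3")
  gt <- rbind(c("hom_ref", "hom_ref", "hom_ref", "hom_alt", "hom_alt", "hom_alt"),
              c("hom_ref", "hom_ref", "hom_ref", "hom_alt", "het", "hom_alt"),
              c("hom_alt", "hom_alt", "hom_alt", "hom_ref", "hom_ref", "hom_ref"),
              c("hom_ref", "hom_ref", "hom_ref", "hom_ref", "hom_ref", "hom_ref"))
  st <- make_table("chr1", c(10, 20, 30, 40), samples = samples, gt = gt)
  res <- group_discriminating(st, samples[1:3], samples[4:6])
  expect_equal(res$pos, c(10, 30))
  expect_equal(res$alt_group, c("B", "A"))
  expect_error(group_discriminating(st, samples[1:3], samples[3:6]), "overlap")
})

test_that("two-sample group discrimination equals the private-SNP filter", {
  set.seed(63)
  n <- 400
  st <- make_table("chr1", seq_len(n) * 7,
                   qual = round(runif(n, 0, 100)),
                   gt = cbind(sample(GT4, n, TRUE), sample(GT4, n, TRUE)),
                   dp = cbind(sample(0:40, n, TRUE), sample(0:40, n, TRUE)),
                   gq = cbind(sample(0:99, n, TRUE), sample(0:99, n, TRUE)))
  a <- classify_private(st, "A", "B")
  b <- group_discriminating(st, "A", "B")
  expect_equal(b$pos, a$snps$pos)
  expect_equal(b$alt_group == "A", a$snps$private_to == "A")
})

test_that("heterozygosity scan flags bins by the max/min clauses", {
  lay <- genome_layout("chr1", 3e5)
  samples <- paste0("S", 1:6)
  hets <- c(25, 15, 14, 14, 16, 18)
  rows <- list()
  for (j in seq_along(samples)) {
    rows[[j]] <- c(rep("het", hets[j]), rep("hom_ref", max(hets) - hets[j]))
  }
  gt <- do.call(cbind, rows)
  st <- make_table("chr1", seq_len(max(hets)) * 100, samples = samples, gt = gt)
  flags <- het_scan(st, lay, width = 1e5, het_high = 20, het_all = 14)
  expect_equal(nrow(flags$flagged), 1L)
  expect_equal(flags$flagged$start, 0)
  expect_equal(unname(unlist(flags$flagged[, samples])), hets)

  # min over samples below het_all -> not flagged
  gt2 <- gt; gt2[13:25, 2] <- "hom_ref"
  st2 <- make_table("chr1", seq_len(max(hets)) * 100, samples = samples, gt = gt2)
  expect_equal(nrow(het_scan(st2, lay, width = 1e5)$flagged), 0L)

  # all-homozygous table has no flags
  st3 <- make_table("chr1", seq_len(10) * 100, samples = samples, gt = "hom_ref")
  expect_equal(nrow(het_scan(st3, lay, width = 1e5)$flagged), 0L)
})
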