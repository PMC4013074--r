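test_that("panel membership partitions by exact position", {
  snps <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  panel <- structure(data.frame(chrom = "chr1", pos = 200,
                                ref = "C", alt = "T"),
                     class = c("panel_index", "data.frame"))
  pm <- panel_membership(snps, panel)
  expect_equal(nrow(pm$member), 1L)
  expect_equal(nrow(pm$novel), 2L)
  expect_equal(pm$fraction_pct, 33.3)
  # disjoint partition covering the input
  expect_equal(sum(pm$in_panel) + sum(!pm$in_panel), nrow(snps))

  # allele-aware: same position, different alt -> novel
  snps2 <- data.frame(chrom = "chr1", pos = 200, ref = "C", alt = "G")
  expect_equal(sum(panel_membership(snps2, panel, allele_aware = TRUE)$in_panel), 0)
  expect_true(is.na(panel_membership(snps[0, ], panel)$fraction_pct))
})

test_that("panel fraction over a seeded binomial draw matches its probability", {
  sim <- simulate_nil(sim_config(seed = 41, n_denovo_b = 5000, n_denovo_a = 0,
                                 blocks = data.frame(chrom = character(0),
                                                     start = numeric(0),
                                                     end = numeric(0)),
                                 p_panel_denovo = 0.705, n_background = 0),
                      outdir = tempfile())
  snps <- sim$truth$snps
  panel <- read_panel(sim$paths$panel)
  pm <- panel_membership(snps, panel)
  se <- sqrt(0.705 * 0.295 / 5000)
  expect_lt(abs(pm$fraction_pct / 100 - 0.705), 3 * se)
})

test_that("de novo derivation excludes panel members and interval SNPs", {
  snps <- data.frame(chrom = "chr1", pos = c(100, 5000, 150000),
                     ref = "C", alt = "T")
  panel <- structure(data.frame(chrom = "chr1", pos = 100),
                     class = c("panel_index", "data.frame"))
  iv <- data.frame(chrom = "chr1", start = 100000, end = 200000)
  expect_equal(derive_denovo(snps, panel, iv)$pos, 5000)
  expect_equal(derive_denovo(snps, panel, iv, exclude_intervals = FALSE)$pos,
               c(5000, 150000))
})

test_that("spectrum collapses strands and conserves counts", {
  expect_equal(unname(mutation_spectrum(
    data.frame(ref = c("C", "G"), alt = c("T", "A")))),
    c(2L, 0L, 0L, 0L, 0L, 0L))
  # one SNP of each of the 12 raw substitution types -> each class twice
  raw <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  raw <- raw[raw$ref != raw$alt, ]
  sp <- mutation_spectrum(raw)
  expect_true(all(sp == 2L))
  expect_equal(sum(sp), nrow(raw))
  # complementing both alleles never changes the class
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(substitution_class(unname(comp[raw$ref]), unname(comp[raw$alt])),
               substitution_class(raw$ref, raw$alt))
  expect_error(mutation_spectrum(data.frame(ref = "N", alt = "A")), "ACGT")
})

test_that("simulated spectrum fractions recover the configured weights", {
  w <- c(0.5, 0.2, 0.1, 0.08, 0.07, 0.05)
  sim <- simulate_nil(sim_config(seed = 43, n_denovo_b = 1000, n_denovo_a = 0,
                                 blocks = data.frame(chrom = character(0),
                                                     start = numeric(0),
                                                     end = numeric(0)),
                                 spectrum_weights = w, n_background = 0),
                      outdir = tempfile())
  dn <- sim$truth$snps
  sp <- mutation_spectrum(dn)
  expect_equal(sum(sp), 1000L)
  expect_equal(names(which.max(sp)), "GC>AT")
  frac <- sp / 1000
  se <- sqrt(w * (1 - w) / 1000)
  expect_true(all(abs(frac - w) < 3 * se))
})

test_that("mutation-rate arithmetic gives per-generation and distance estimates", {
  m <- mutation_rate_model(7e-9, 2.3e9)
  expect_equal(mutations_per_generation(m), 16.1)
  expect_equal(mutations_per_generation(mutation_rate_model(1e-9, 1e9)), 1.0)
  # monotone in both arguments
  expect_gt(mutations_per_generation(mutation_rate_model(8e-9, 2.3e9)), 16.1)
  expect_gt(mutations_per_generation(mutation_rate_model(7e-9, 3e9)), 16.1)

  expect_equal(generations_removed(358, m), 22L)
  expect_equal(generations_removed(883, m), 55L)
  expect_equal(generations_removed(0, m), 0L)
})

test_that("generation estimator recovers simulated distances", {
  model <- mutation_rate_model()
  rate <- mutations_per_generation(model)
  set.seed(44)
  for (g in c(5, 22, 55)) {
    n_mut <- rpois(20, g * rate)
    est <- generations_removed(n_mut, model)
    tol <- 3 * sqrt(g / 16)
    expect_lt(abs(mean(est) - g), tol)
    expect_gte(mean(abs(est - g) <= tol), 0.95)
  }
})
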