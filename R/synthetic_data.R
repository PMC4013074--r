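# Synthetic-data generator with ground truth.
#
# Emulates the statistical structure the analysis assumes: a desk-scale
# multi-chromosome genome carrying a few planted introgression blocks of
# strongly elevated homozygous-divergent SNP density in one line, sparse
# genome-wide de novo mutations with a transition-biased spectrum in both
# lines, haplotype-panel membership probabilities that differ sharply
# between introgressed and de novo SNPs, filter-rejectable background
# noise sites, per-site depth/quality noise, and a transcribed subset
# genotyped in replicated RNA-seq samples. Everything is deterministic for
# a fixed seed, and the generator records complete ground truth so every
# downstream stage can be validated exactly.

#' Default simulation configuration
#'
#' The defaults define the generator's study conditions: a 10 x 20 Mb
#' genome; three introgression blocks (1.1, 0.5 and 3.0 Mb) private to
#' line B at 9e-4 SNPs/bp (~0.9 SNPs per kb, the density regime of a real
#' introgressed segment against ~zero background); 31 and 77 de novo
#' SNPs in lines A and B — genome-scale de novo densities
#' (358 and 883 over 2.3 Gbp) preserved per bp at desk scale, so bins
#' exceeding the scan threshold occur essentially only inside blocks;
#' a transition-biased substitution spectrum with
#' G:C->A:T heaviest; panel-membership probability 0.75 for introgressed
#' and 0.05 for de novo SNPs; 500 background sites each violating at least
#' one filter criterion; negative-binomial sequencing depth (mean 30,
#' size 8) floored at the calling threshold for planted sites; 10% of
#' sites transcribed; three RNA-seq replicates per line; and a 1000-gene
#' DE table with 121 true DE genes, nine of them inside the planted
#' blocks.
#'
#' @param seed Integer seed; the full bundle is a deterministic function
#'   of it.
#' @param n_chrom,chrom_mb Genome shape (default 10 chromosomes x 20 Mb).
#' @param blocks data.frame `chrom`, `start`, `end` (0-based bp) of
#'   planted introgression blocks; NULL uses the three defaults.
#' @param block_density SNPs per bp inside blocks (default 9e-4).
#' @param n_denovo_a,n_denovo_b Planted de novo counts (defaults 31, 77).
#' @param spectrum_weights Probabilities over the six collapsed
#'   substitution classes, in [mutation_spectrum()] order.
#' @param p_panel_introgression,p_panel_denovo Panel-membership
#'   probabilities (defaults 0.75, 0.05).
#' @param n_panel_decoys Panel positions not coinciding with any SNP
#'   (default 3000).
#' @param n_background Filter-rejectable noise sites (default 500).
#' @param depth_mean,depth_size Negative-binomial depth model (defaults
#'   30, 8).
#' @param transcribed_fraction Fraction of SNP sites covered by RNA-seq
#'   (default 0.1).
#' @param n_replicates RNA-seq replicates per line (default 3).
#' @param rna_geno_error Per-call probability an RNA genotype is corrupted
#'   to het (default 0).
#' @param n_genes,n_de,n_de_in_blocks DE-table shape (defaults 1000, 121,
#'   9).
#' @param exon_n,exon_width Exon annotation shape (defaults 5000 exons of
#'   2 kb).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 10, chrom_mb = 20,
                       blocks = NULL, block_density = 9e-4,
                       n_denovo_a = 31, n_denovo_b = 77,
                       spectrum_weights = c(0.50, 0.20, 0.10, 0.08, 0.07, 0.05),
                       p_panel_introgression = 0.75, p_panel_denovo = 0.05,
                       n_panel_decoys = 3000,
                       n_background = 500,
                       depth_mean = 30, depth_size = 8,
                       transcribed_fraction = 0.1, n_replicates = 3,
                       rna_geno_error = 0,
                       n_genes = 1000, n_de = 121, n_de_in_blocks = 9,
                       exon_n = 5000, exon_width = 2000) {
  layout <- genome_layout(paste0("chr", seq_len(n_chrom)),
                          rep(chrom_mb * 1e6, n_chrom))
  if (is.null(blocks)) {
    blocks <- data.frame(
      chrom = c("chr1", "chr5", "chr10"),
      start = c(14.0e6, 8.1e6, 12.3e6),
      end = c(15.1e6, 8.6e6, 15.3e6),
      stringsAsFactors = FALSE)
  }
  if (nrow(blocks)) {
    len <- chrom_length(layout, blocks$chrom)
    if (any(blocks$start < 0) || any(blocks$end > len) ||
        any(blocks$start >= blocks$end)) {
      stop("introgression block outside layout")
    }
  }
  stopifnot(length(spectrum_weights) == 6,
            abs(sum(spectrum_weights) - 1) < 1e-8,
            p_panel_introgression >= 0, p_panel_introgression <= 1,
            p_panel_denovo >= 0, p_panel_denovo <= 1,
            transcribed_fraction >= 0, transcribed_fraction <= 1)
  structure(list(seed = seed, layout = layout, blocks = blocks,
                 block_density = block_density,
                 n_denovo_a = n_denovo_a, n_denovo_b = n_denovo_b,
                 spectrum_weights = spectrum_weights,
                 p_panel_introgression = p_panel_introgression,
                 p_panel_denovo = p_panel_denovo,
                 n_panel_decoys = n_panel_decoys,
                 n_background = n_background,
                 depth_mean = depth_mean, depth_size = depth_size,
                 transcribed_fraction = transcribed_fraction,
                 n_replicates = n_replicates,
                 rna_geno_error = rna_geno_error,
                 n_genes = n_genes, n_de = n_de,
                 n_de_in_blocks = n_de_in_blocks,
                 exon_n = exon_n, exon_width = exon_width),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# draw (ref, alt) pairs following the collapsed-class weights; within a
# class the two strand orientations are equally likely
draw_spectrum_alleles <- function(n, weights) {
  pairs <- list("GC>AT" = list(c("C", "T"), c("G", "A")),
                "AT>GC" = list(c("T", "C"), c("A", "G")),
                "GC>TA" = list(c("C", "A"), c("G", "T")),
                "GC>CG" = list(c("C", "G"), c("G", "C")),
                "AT>TA" = list(c("T", "A"), c("A", "T")),
                "AT>CG" = list(c("T", "G"), c("A", "C")))
  cls <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = weights)
  strand <- sample(1:2, n, replace = TRUE)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    p <- pairs[[cls[i]]][[strand[i]]]
    ref[i] <- p[1]; alt[i] <- p[2]
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# sample unique genome-wide positions uniformly, avoiding `taken` keys
sample_positions <- function(n, layout, taken = character(0)) {
  chrom <- character(0); pos <- numeric(0)
  total <- genome_size(layout)
  cum <- cumsum(layout$length)
  while (length(pos) < n) {
    need <- n - length(pos)
    g <- floor(stats::runif(need * 2 + 10) * total)
    ci <- findInterval(g, cum) + 1L
    p <- g - c(0, cum)[ci]
    key <- paste(layout$name[ci], p)
    ok <- !duplicated(key) & !(key %in% taken)
    chrom <- c(chrom, layout$name[ci][ok])
    pos <- c(pos, p[ok])
    taken <- c(taken, key[ok])
    if (length(pos) > n) { chrom <- chrom[1:n]; pos <- pos[1:n] }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate a full nearly-isogenic-line sequencing experiment
#'
#' Generates the complete input bundle for the pipeline — paired WGS VCF
#' (samples `A`, `B`), multi-sample RNA-seq VCF (replicates `A1..`,
#' `B1..`), haplotype-panel TSV, exon BED, DE-gene table, genome-layout
#' TSV — together with the ground truth needed to validate every stage.
#' The output is a deterministic function of `config$seed`: the same
#' configuration always produces a byte-identical bundle.
#'
#' @param config A [sim_config()].
#' @param outdir Directory for the file bundle (created if needed).
#' @return List with `paths` (named file paths) and `truth` (list:
#'   `snps` data.frame with per-SNP `label`
#'   (`introgression`/`denovo_a`/`denovo_b`/`background`), `in_panel`,
#'   `transcribed`; `blocks`; `de_genes` with `true_de`; `config`).
#' @export
simulate_nil <- function(config = sim_config(), outdir = tempfile("nilsim")) {
  set.seed(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  layout <- config$layout

  # --- planted SNPs ---------------------------------------------------
  intro <- do.call(rbind, c(list(
    data.frame(chrom = character(0), pos = numeric(0),
               label = character(0), stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(config$blocks)), function(i) {
      b <- config$blocks[i, ]
      n <- stats::rpois(1, config$block_density * (b$end - b$start))
      pos <- sort(sample.int(b$end - b$start, n) - 1L + b$start)
      data.frame(chrom = rep(b$chrom, n), pos = pos,
                 label = rep("introgression", n), stringsAsFactors = FALSE)
    })))
  taken <- paste(intro$chrom, intro$pos)

  dn_a <- sample_positions(config$n_denovo_a, layout, taken)
  dn_a$label <- rep("denovo_a", nrow(dn_a))
  taken <- c(taken, paste(dn_a$chrom, dn_a$pos))
  dn_b <- sample_positions(config$n_denovo_b, layout, taken)
  dn_b$label <- rep("denovo_b", nrow(dn_b))
  taken <- c(taken, paste(dn_b$chrom, dn_b$pos))
  bg <- sample_positions(config$n_background, layout, taken)
  bg$label <- rep("background", nrow(bg))
  taken <- c(taken, paste(bg$chrom, bg$pos))

  snps <- rbind(intro, dn_a, dn_b, bg)
  if (nrow(snps) == 0L) stop("configuration generates no SNPs at all")

  # alleles: de novo SNPs follow the configured spectrum; others uniform
  n_all <- nrow(snps)
  ref <- sample(BASES, n_all, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
  is_dn <- snps$label %in% c("denovo_a", "denovo_b")
  if (any(is_dn)) {
    sp <- draw_spectrum_alleles(sum(is_dn), config$spectrum_weights)
    ref[is_dn] <- sp$ref; alt[is_dn] <- sp$alt
  }
  snps$ref <- ref; snps$alt <- unname(alt)

  # --- genotypes, depth, quality --------------------------------------
  gt_a <- ifelse(snps$label %in% c("denovo_a"), "hom_alt", "hom_ref")
  gt_b <- ifelse(snps$label %in% c("introgression", "denovo_b"),
                 "hom_alt", "hom_ref")
  rdep <- function(n) stats::rnbinom(n, size = config$depth_size,
                                     mu = config$depth_mean)
  dp_a <- rdep(n_all); dp_b <- rdep(n_all)
  qual <- round(stats::runif(n_all, 60, 250), 1)
  gq_a <- round(stats::runif(n_all, 30, 99)); gq_b <- round(stats::runif(n_all, 30, 99))

  planted <- snps$label != "background"
  # planted sites must survive the filter: floor depth at the calling minimum
  dp_a[planted] <- pmax(dp_a[planted], 10)
  dp_b[planted] <- pmax(dp_b[planted], 10)

  # background sites each violate >=1 retention criterion
  if (any(!planted)) {
    modes <- sample(c("low_depth", "low_qual", "het", "low_gq", "same_geno"),
                    sum(!planted), replace = TRUE)
    idx <- which(!planted)
    for (k in seq_along(idx)) {
      i <- idx[k]
      switch(modes[k],
        low_depth = if (stats::runif(1) < 0.5) dp_a[i] <- sample(0:9, 1)
                    else dp_b[i] <- sample(0:9, 1),
        low_qual = qual[i] <- round(stats::runif(1, 0, 39.9), 1),
        het = if (stats::runif(1) < 0.5) gt_a[i] <- "het" else gt_b[i] <- "het",
        low_gq = if (stats::runif(1) < 0.5) gq_a[i] <- sample(0:9, 1)
                 else gq_b[i] <- sample(0:9, 1),
        same_geno = gt_a[i] <- gt_b[i])
      if (modes[k] %in% c("low_depth", "het", "low_gq") &&
          gt_a[i] == gt_b[i]) {
        gt_b[i] <- ifelse(gt_a[i] == "hom_ref", "hom_alt", "hom_ref")
      }
    }
    snps$bg_mode <- NA_character_
    snps$bg_mode[idx] <- modes
  } else {
    snps$bg_mode <- NA_character_
  }

  # --- panel membership -----------------------------------------------
  p_mem <- rep(0, n_all)
  p_mem[snps$label == "introgression"] <- config$p_panel_introgression
  p_mem[is_dn] <- config$p_panel_denovo
  snps$in_panel <- stats::runif(n_all) < p_mem

  # --- transcribed subset ---------------------------------------------
  snps$transcribed <- stats::runif(n_all) < config$transcribed_fraction
  reps <- c(paste0("A", seq_len(config$n_replicates)),
            paste0("B", seq_len(config$n_replicates)))

  # --- write bundle ----------------------------------------------------
  paths <- list(
    layout = file.path(outdir, "layout.tsv"),
    wgs_vcf = file.path(outdir, "wgs.vcf"),
    rna_vcf = file.path(outdir, "rna.vcf"),
    panel = file.path(outdir, "panel.tsv"),
    exons = file.path(outdir, "exons.bed"),
    de_table = file.path(outdir, "de_genes.tsv"),
    truth = file.path(outdir, "truth.json"))

  writeLines(sprintf("%s\t%d", layout$name, as.integer(layout$length)),
             paths$layout)

  ord <- order(chrom_rank(layout, snps$chrom), snps$pos)
  snps <- snps[ord, , drop = FALSE]; rownames(snps) <- NULL
  gt_a <- gt_a[ord]; gt_b <- gt_b[ord]
  dp_a <- dp_a[ord]; dp_b <- dp_b[ord]
  gq_a <- gq_a[ord]; gq_b <- gq_b[ord]
  qual <- qual[ord]

  write_sim_vcf(paths$wgs_vcf, layout, snps, qual,
                samples = c("A", "B"),
                gt = cbind(gt_a, gt_b), dp = cbind(dp_a, dp_b),
                gq = cbind(gq_a, gq_b))

  rna_sites <- which(snps$transcribed)
  rna_gt <- matrix("missing", nrow = length(rna_sites), ncol = length(reps),
                   dimnames = list(NULL, reps))
  for (j in seq_along(reps)) {
    line_gt <- if (startsWith(reps[j], "A")) gt_a else gt_b
    rna_gt[, j] <- line_gt[rna_sites]
  }
  if (config$rna_geno_error > 0) {
    err <- matrix(stats::runif(length(rna_gt)) < config$rna_geno_error,
                  nrow = nrow(rna_gt))
    rna_gt[err] <- "het"
  }
  rna_dp <- matrix(rdep(length(rna_sites) * length(reps)),
                   nrow = length(rna_sites), dimnames = list(NULL, reps))
  rna_gq <- matrix(round(stats::runif(length(rna_sites) * length(reps), 30, 99)),
                   nrow = length(rna_sites), dimnames = list(NULL, reps))
  write_sim_vcf(paths$rna_vcf, layout, snps[rna_sites, , drop = FALSE],
                qual[rna_sites], samples = reps,
                gt = rna_gt, dp = rna_dp, gq = rna_gq)

  # panel: member SNP positions plus decoys
  mem <- snps[snps$in_panel, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  dec <- sample_positions(config$n_panel_decoys, layout,
                          paste(snps$chrom, snps$pos))
  dec$ref <- sample(BASES, nrow(dec), replace = TRUE)
  dec$alt <- vapply(dec$ref, function(r) sample(setdiff(BASES, r), 1), "")
  panel <- rbind(mem, dec[, c("chrom", "pos", "ref", "alt")])
  panel <- panel[order(chrom_rank(layout, panel$chrom), panel$pos), ]
  con <- file(paths$panel, "w")
  writeLines("chrom\tpos\tref\talt", con)
  writeLines(sprintf("%s\t%d\t%s\t%s", panel$chrom,
                     as.integer(panel$pos) + 1L, panel$ref, panel$alt), con)
  close(con)

  # exon annotation
  ex <- sample_positions(config$exon_n, layout)
  ex$start <- pmin(ex$pos, chrom_length(layout, ex$chrom) - config$exon_width)
  ex$end <- ex$start + config$exon_width
  ex <- ex[order(chrom_rank(layout, ex$chrom), ex$start), ]
  con <- file(paths$exons, "w")
  writeLines("#chrom\tstart\tend\tid", con)
  writeLines(sprintf("%s\t%d\t%d\texon%06d", ex$chrom,
                     as.integer(ex$start), as.integer(ex$end),
                     seq_len(nrow(ex))), con)
  close(con)

  # DE-gene table: n_de true DE genes, n_de_in_blocks of them inside the
  # planted blocks; non-DE genes fail both thresholds
  de <- sim_de_table(config, layout)
  utils::write.table(de, paths$de_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- list(snps = snps, blocks = config$blocks, de_genes = de,
                rna_replicates = reps, config = config)
  truth_json <- list(
    blocks = config$blocks,
    n_introgression = sum(snps$label == "introgression"),
    n_denovo_a = sum(snps$label == "denovo_a"),
    n_denovo_b = sum(snps$label == "denovo_b"),
    n_background = sum(snps$label == "background"),
    n_panel_members = sum(snps$in_panel),
    n_transcribed = sum(snps$transcribed),
    n_true_de = sum(de$true_de))
  write_report(truth_json, paths$truth)

  list(paths = paths, truth = truth)
}

sim_de_table <- function(config, layout) {
  n <- config$n_genes
  gene_w <- 2000 + floor(stats::runif(n) * 6000)
  loc <- sample_positions(n, layout)
  loc$start <- pmin(loc$pos, chrom_length(layout, loc$chrom) - gene_w)
  loc$end <- loc$start + gene_w
  true_de <- rep(FALSE, n)
  true_de[seq_len(config$n_de)] <- TRUE
  # place the first n_de_in_blocks DE genes inside planted blocks
  nb <- min(config$n_de_in_blocks, config$n_de, nrow(config$blocks) * 50)
  if (nb > 0 && nrow(config$blocks)) {
    bi <- rep_len(seq_len(nrow(config$blocks)), nb)
    for (k in seq_len(nb)) {
      b <- config$blocks[bi[k], ]
      s <- b$start + floor(stats::runif(1) * max(1, b$end - b$start - gene_w[k]))
      loc$chrom[k] <- b$chrom
      loc$start[k] <- s
      loc$end[k] <- s + gene_w[k]
    }
  }
  lfc <- numeric(n); q <- numeric(n)
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  lfc[true_de] <- (sgn * stats::runif(n, 2, 6))[true_de]
  q[true_de] <- stats::runif(sum(true_de), 0, 0.049)
  lfc[!true_de] <- (sgn * stats::runif(n, 0, 1.9))[!true_de]
  q[!true_de] <- stats::runif(sum(!true_de), 0.051, 1)
  fpkm_b <- round(stats::runif(n, 0.1, 50), 2)
  fpkm_a <- round(fpkm_b * 2^lfc, 2)
  data.frame(gene_id = sprintf("GENE%05d", seq_len(n)),
             chrom = loc$chrom, start = loc$start, end = loc$end,
             fpkm_a = fpkm_a, fpkm_b = fpkm_b,
             log2fc = round(lfc, 4), q_value = signif(q, 6),
             true_de = true_de, stringsAsFactors = FALSE)
}

GT_STRING <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")

# minimal deterministic VCF 4.2 text emitter (GT:DP:GQ)
write_sim_vcf <- function(path, layout, snps, qual, samples, gt, dp, gq) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=nilscan-simulator", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", layout$name,
                     as.integer(layout$length)), con)
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
    con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(snps)) {
    cells <- vapply(seq_along(samples), function(j) {
      paste(GT_STRING[gt[, j]], as.integer(dp[, j]), as.integer(gq[, j]),
            sep = ":")
    }, character(nrow(snps)))
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(snps))
    lines <- paste(snps$chrom, as.integer(snps$pos) + 1L, ".", snps$ref,
                   snps$alt, format(qual, trim = TRUE, scientific = FALSE),
                   "PASS", ".", "GT:DP:GQ",
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
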