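# Two-sample discriminating-SNP filter: the standard variant-retention rule
# for paired resequencing of nearly-isogenic lines. A site is retained when
# both samples are confidently homozygous, for different alleles.

#' Filter thresholds for discriminating SNPs
#'
#' Defaults reproduce the standard paired-sample retention rule: at least
#' 10-fold read coverage in both samples, site quality at least 40, both
#' genotypes homozygous with genotype quality at least 10, and the two
#' genotypes different.
#'
#' @param min_depth Minimum per-sample read depth (default 10).
#' @param min_site_quality Minimum site (VCF QUAL) score (default 40).
#' @param min_genotype_quality Minimum per-sample genotype quality
#'   (default 10).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_depth = 10, min_site_quality = 40,
                              min_genotype_quality = 10) {
  stopifnot(min_depth >= 0, min_site_quality >= 0, min_genotype_quality >= 0)
  structure(list(min_depth = min_depth,
                 min_site_quality = min_site_quality,
                 min_genotype_quality = min_genotype_quality),
            class = "filter_thresholds")
}

#' Discriminating-site predicate
#'
#' Vectorized over sites. TRUE iff both depths meet `min_depth`, site
#' quality meets `min_site_quality`, both genotypes are homozygous
#' (`hom_ref` or `hom_alt`; het and missing always fail) with genotype
#' quality at least `min_genotype_quality`, and the two genotypes differ.
#'
#' @param site_quality Numeric vector of site qualities.
#' @param gt_a,gt_b Genotype classes for the two samples
#'   (`hom_ref`/`het`/`hom_alt`/`missing`).
#' @param dp_a,dp_b Read depths.
#' @param gq_a,gq_b Genotype qualities.
#' @param thresholds A [filter_thresholds()] object.
#' @return Logical vector.
#' @export
site_passes <- function(site_quality, gt_a, gt_b, dp_a, dp_b, gq_a, gq_b,
                        thresholds = filter_thresholds()) {
  t <- thresholds
  hom <- function(g) g %in% c("hom_ref", "hom_alt")
  dp_a >= t$min_depth & dp_b >= t$min_depth &
    site_quality >= t$min_site_quality &
    hom(gt_a) & hom(gt_b) &
    gq_a >= t$min_genotype_quality & gq_b >= t$min_genotype_quality &
    gt_a != gt_b
}

#' Classify private (line-discriminating) SNPs between two samples
#'
#' Applies [site_passes()] to every site of a two-sample comparison and
#' assigns each retained SNP to the line carrying the non-reference allele
#' (the `hom_alt` sample). The two private sets partition the retained
#' SNPs: `count_a + count_b` equals the total retained.
#'
#' @param st A `site_table` containing both samples.
#' @param sample_a,sample_b Sample names in `st`.
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `snps` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `private_to`), `counts` (named integer vector for the two
#'   samples), `n_retained`, `n_input`.
#' @export
classify_private <- function(st, sample_a, sample_b,
                             thresholds = filter_thresholds()) {
  miss <- setdiff(c(sample_a, sample_b), st$samples)
  if (length(miss)) {
    stop("sample(s) not in table: ", paste(miss, collapse = ", "),
         "; available: ", paste(st$samples, collapse = ", "))
  }
  ga <- st$gt[, sample_a]; gb <- st$gt[, sample_b]
  pass <- site_passes(st$sites$qual, ga, gb,
                      st$dp[, sample_a], st$dp[, sample_b],
                      st$gq[, sample_a], st$gq[, sample_b], thresholds)
  snps <- st$sites[pass, , drop = FALSE]
  snps$private_to <- ifelse(ga[pass] == "hom_alt", sample_a, sample_b)
  rownames(snps) <- NULL
  counts <- c(sum(snps$private_to == sample_a),
              sum(snps$private_to == sample_b))
  names(counts) <- c(sample_a, sample_b)
  list(snps = snps, counts = counts,
       n_retained = nrow(snps), n_input = n_sites(st))
}
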