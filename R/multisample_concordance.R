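# RNA-seq replicate genotyping at known variant positions, concordance with
# the whole-genome calls, multi-sample discriminating-SNP discovery across
# replicate groups, and a per-bin heterozygosity scan for residual
# heterozygosity / collapsed paralogs.

#' Genotype samples at target sites
#'
#' For each target position and sample, the pre-called genotype is used
#' when its read depth meets `min_depth`; below that the call is set to
#' missing. When a sample has no call at a target (position absent from the
#' table, e.g. untranscribed) the call is missing. An optional fallback
#' caller re-genotypes from allele depths: homozygous when the major-allele
#' fraction is at least `hom_frac`, heterozygous when the minor fraction is
#' at least `het_frac`, otherwise missing.
#'
#' @param st A `site_table` of sample calls (e.g. parsed RNA-seq VCF).
#' @param targets data.frame with `chrom`, `pos` (0-based) target
#'   positions.
#' @param min_depth Minimum reads for a call (default 10).
#' @param allele_depths Optional list of two site-by-sample matrices
#'   `ref` and `alt`; when supplied the fallback caller is used instead of
#'   the pre-called genotypes.
#' @param hom_frac,het_frac Fallback-caller thresholds (defaults 0.9, 0.2).
#' @return Character matrix (targets x samples) of 4-class genotype calls.
#' @export
genotype_at_sites <- function(st, targets, min_depth = 10,
                              allele_depths = NULL,
                              hom_frac = 0.9, het_frac = 0.2) {
  key_t <- paste(targets$chrom, targets$pos)
  key_s <- paste(st$sites$chrom, st$sites$pos)
  idx <- match(key_t, key_s)
  out <- matrix("missing", nrow = nrow(targets), ncol = length(st$samples),
                dimnames = list(NULL, st$samples))
  hit <- which(!is.na(idx))
  if (!length(hit)) return(out)
  rows <- idx[hit]
  if (is.null(allele_depths)) {
    g <- st$gt[rows, , drop = FALSE]
    d <- st$dp[rows, , drop = FALSE]
    g[d < min_depth] <- "missing"
    out[hit, ] <- g
  } else {
    rd <- allele_depths$ref[rows, , drop = FALSE]
    ad <- allele_depths$alt[rows, , drop = FALSE]
    tot <- rd + ad
    g <- matrix("missing", nrow = length(rows), ncol = length(st$samples))
    maj <- pmax(rd, ad) / ifelse(tot > 0, tot, 1)
    minr <- pmin(rd, ad) / ifelse(tot > 0, tot, 1)
    hom <- tot >= min_depth & maj >= hom_frac
    het <- tot >= min_depth & !hom & minr >= het_frac
    g[hom & rd >= ad] <- "hom_ref"
    g[hom & ad > rd] <- "hom_alt"
    g[het] <- "het"
    out[hit, ] <- g
  }
  out
}

#' Concordance of replicate genotype calls with expected genotypes
#'
#' A target site is "typed" when every replicate of the group has a
#' non-missing call and the replicates are unanimous. Typed sites are
#' classified by that consensus against the expected genotype
#' (conventionally `hom_alt`, the non-reference allele of the private SNP):
#' `n_match_expected + n_other_allele + n_het = n_typed`. Sites called in
#' all replicates but not unanimously are listed as replicate-discordant
#' and excluded from the tallies.
#'
#' @param calls Character matrix (targets x replicates) from
#'   [genotype_at_sites()].
#' @param targets data.frame of target positions (row-parallel to
#'   `calls`); used to label discordant sites.
#' @param expected Expected genotype class per target (scalar or vector;
#'   default `"hom_alt"`).
#' @return List with `n_typed`, `n_match_expected`, `n_other_allele`,
#'   `n_het`, `pct_match` (integer percent), `replicate_discordant`
#'   (data.frame of sites typed-depth but non-unanimous), and
#'   `wgs_discordant` (typed sites whose consensus differs from expected).
#' @export
concordance_report <- function(calls, targets, expected = "hom_alt") {
  stopifnot(nrow(calls) == nrow(targets))
  expected <- rep_len(expected, nrow(calls))
  all_called <- apply(calls != "missing", 1, all)
  unanimous <- apply(calls, 1, function(r) length(unique(r)) == 1L)
  typed <- all_called & unanimous
  consensus <- ifelse(typed, calls[, 1], NA_character_)
  n_match <- sum(typed & consensus == expected)
  n_het <- sum(typed & consensus == "het" & expected != "het")
  n_other <- sum(typed) - n_match - n_het
  list(n_typed = sum(typed),
       n_match_expected = n_match,
       n_other_allele = n_other,
       n_het = n_het,
       pct_match = if (sum(typed) > 0)
         as.integer(round_half_away(100 * n_match / sum(typed))) else NA_integer_,
       replicate_discordant = targets[all_called & !unanimous, , drop = FALSE],
       wgs_discordant = targets[typed & consensus != expected, , drop = FALSE])
}

#' Group-discriminating SNPs across replicate groups
#'
#' Retains sites where every group-A sample is homozygous for one allele
#' and every group-B sample homozygous for the other, with all calls
#' passing the depth/site-quality/genotype-quality thresholds. With one
#' sample per group this reduces exactly to [classify_private()].
#'
#' @param st A multi-sample `site_table`.
#' @param group_a,group_b Disjoint character vectors of sample names.
#' @param thresholds A [filter_thresholds()] object.
#' @return data.frame of retained sites (`chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `alt_group`: the group carrying the alternative allele).
#' @export
group_discriminating <- function(st, group_a, group_b,
                                 thresholds = filter_thresholds()) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  miss <- setdiff(c(group_a, group_b), st$samples)
  if (length(miss)) stop("sample(s) not in table: ", paste(miss, collapse = ", "))
  t <- thresholds
  ok_call <- function(samp) {
    st$gt[, samp] %in% c("hom_ref", "hom_alt") &
      st$dp[, samp] >= t$min_depth & st$gq[, samp] >= t$min_genotype_quality
  }
  qual_ok <- st$sites$qual >= t$min_site_quality
  all_ok <- Reduce(`&`, lapply(c(group_a, group_b), ok_call), qual_ok)
  gA <- st$gt[, group_a, drop = FALSE]
  gB <- st$gt[, group_b, drop = FALSE]
  fixed_a <- apply(gA, 1, function(r) length(unique(r)) == 1L)
  fixed_b <- apply(gB, 1, function(r) length(unique(r)) == 1L)
  differ <- gA[, 1] != gB[, 1]
  keep <- all_ok & fixed_a & fixed_b & differ
  out <- st$sites[keep, , drop = FALSE]
  out$alt_group <- ifelse(gA[keep, 1] == "hom_alt", "A", "B")
  rownames(out) <- NULL
  out
}

#' Per-bin heterozygosity scan
#'
#' Counts heterozygous and homozygous(-alternative) calls per 100 kb bin
#' and per sample, and flags bins where the maximum het count over samples
#' exceeds `het_high` while the minimum over samples is at least
#' `het_all` — the signature of a collapsed paralogous region visible in
#' every sample.
#'
#' @param st A multi-sample `site_table`.
#' @param layout A `genome_layout`.
#' @param width Bin width in bp (default 100000).
#' @param het_high Strict threshold on the per-bin maximum het count
#'   (default 20: flag needs `> 20` in at least one sample).
#' @param het_all Inclusive threshold on the per-bin minimum het count
#'   (default 14: all samples need `>= 14`).
#' @return List with `het_counts` (data.frame: `chrom`, `bin`, `start` and
#'   one column per sample), `hom_counts` (same shape), `flagged`
#'   (data.frame subset of bins meeting both clauses).
#' @export
het_scan <- function(st, layout, width = 100000, het_high = 20, het_all = 14) {
  count_grid <- function(cls) {
    per_sample <- lapply(st$samples, function(s) {
      sel <- st$gt[, s] == cls
      bin_snp_counts(st$sites[sel, , drop = FALSE], layout, width)$count
    })
    base <- bin_snp_counts(st$sites[0, , drop = FALSE], layout, width)
    out <- base[, c("chrom", "bin", "start")]
    out[st$samples] <- per_sample
    out
  }
  het <- count_grid("het")
  hom <- count_grid("hom_alt")
  m <- as.matrix(het[, st$samples, drop = FALSE])
  flag <- apply(m, 1, max) > het_high & apply(m, 1, min) >= het_all
  list(het_counts = het, hom_counts = hom,
       flagged = het[flag, , drop = FALSE])
}
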