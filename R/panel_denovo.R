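# Haplotype-panel intersection and de novo mutation analysis.
#
# Private SNPs present in a many-line haplotype panel are standing
# variation (introgressed); private SNPs absent from the panel and lying
# outside the called introgression intervals are attributed to spontaneous
# mutation during seed propagation. The de novo count, divided by the
# expected mutations per generation (mu x genome size), estimates how many
# propagation cycles separate two genomes.

SPECTRUM_CLASSES <- c("GC>AT", "AT>GC", "GC>TA", "GC>CG", "AT>TA", "AT>CG")

#' Read a haplotype-panel position file
#'
#' @param path Tab-separated file with columns chrom, pos (1-based), and
#'   optionally ref, alt. A header line starting with `chrom` or `#` is
#'   skipped.
#' @return A `panel_index` data.frame with `chrom`, `pos` (0-based) and,
#'   when present, `ref`, `alt`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- length(lines) > 0 &&
    (startsWith(lines[1], "#") || grepl("^chrom\\b", lines[1]))
  if (hdr) lines <- lines[-1]
  if (!length(lines)) {
    return(structure(data.frame(chrom = character(0), pos = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("panel_index", "data.frame")))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  out <- data.frame(chrom = parts[, 1], pos = as.numeric(parts[, 2]) - 1,
                    stringsAsFactors = FALSE)
  if (ncol(parts) >= 4) { out$ref <- parts[, 3]; out$alt <- parts[, 4] }
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_index", "data.frame")
  out
}

panel_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Partition SNPs by haplotype-panel membership
#'
#' Exact-position lookup by default; with `allele_aware = TRUE` the
#' alternative allele must also match the panel record.
#'
#' @param snps data.frame with `chrom`, `pos` (0-based) and, for
#'   allele-aware matching, `alt`.
#' @param panel A `panel_index` from [read_panel()].
#' @param allele_aware Require the alt allele to match (default FALSE).
#' @return List with logical `in_panel` per SNP, subsets `member` and
#'   `novel`, and `fraction_pct` (percent in panel, one decimal; `NA` for
#'   an empty SNP set).
#' @export
panel_membership <- function(snps, panel, allele_aware = FALSE) {
  if (nrow(snps) == 0) {
    return(list(in_panel = logical(0), member = snps, novel = snps,
                fraction_pct = NA_real_))
  }
  hit <- panel_key(snps$chrom, snps$pos) %in% panel_key(panel$chrom, panel$pos)
  if (allele_aware) {
    if (is.null(panel$alt)) stop("panel has no allele columns for allele-aware matching")
    key_al <- paste(panel_key(panel$chrom, panel$pos), panel$alt)
    hit <- paste(panel_key(snps$chrom, snps$pos), snps$alt) %in% key_al
  }
  list(in_panel = hit,
       member = snps[hit, , drop = FALSE],
       novel = snps[!hit, , drop = FALSE],
       fraction_pct = pct1(sum(hit), length(hit)))
}

#' Derive the de novo SNP set
#'
#' De novo SNPs are private to one line, absent from the haplotype panel,
#' and (by default) outside the called introgression intervals — a SNP
#' inside an introgressed segment is standing variation from the donor even
#' when the panel happens not to catalogue it.
#'
#' @param private_snps data.frame with `chrom`, `pos` (0-based) for one
#'   line's private set.
#' @param panel A `panel_index`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); may be empty.
#' @param exclude_intervals Drop SNPs inside `intervals` (default TRUE).
#' @param allele_aware Passed to [panel_membership()].
#' @return data.frame: the de novo subset of `private_snps`.
#' @export
derive_denovo <- function(private_snps, panel, intervals = NULL,
                          exclude_intervals = TRUE, allele_aware = FALSE) {
  pm <- panel_membership(private_snps, panel, allele_aware = allele_aware)
  out <- pm$novel
  if (exclude_intervals && !is.null(intervals) && nrow(intervals) &&
      nrow(out)) {
    inside <- snps_in_intervals(out, intervals)
    out <- out[!inside, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# logical: is each SNP position inside any interval (0-based half-open)?
snps_in_intervals <- function(snps, intervals) {
  if (!nrow(snps) || !nrow(intervals)) return(rep(FALSE, nrow(snps)))
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(start = snps$pos + 1, width = 1))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(start = intervals$start + 1,
                                               end = intervals$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Strand-collapsed substitution spectrum
#'
#' Each SNP maps to one of the six collapsed classes; complementary
#' substitutions count together (C>T and G>A are both G:C->A:T).
#'
#' @param snps data.frame with single-base `ref` and `alt` columns.
#' @return Named integer vector over the six classes `GC>AT`, `AT>GC`,
#'   `GC>TA`, `GC>CG`, `AT>TA`, `AT>CG`; sums to `nrow(snps)`.
#' @export
mutation_spectrum <- function(snps) {
  counts <- stats::setNames(integer(length(SPECTRUM_CLASSES)), SPECTRUM_CLASSES)
  if (!nrow(snps)) return(counts)
  cls <- substitution_class(snps$ref, snps$alt)
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  counts[] <- as.integer(tab)
  counts
}

#' Collapsed substitution class of ref>alt pairs
#' @param ref,alt Single-base character vectors.
#' @return Character vector of classes (see [mutation_spectrum()]).
#' @export
substitution_class <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stop("non-ACGT or degenerate ref/alt allele")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # pyrimidine-standardize: express every substitution with ref in {C,T}
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  key <- paste0(r, a)
  map <- c(CT = "GC>AT", TC = "AT>GC", CA = "GC>TA",
           CG = "GC>CG", TA = "AT>TA", TG = "AT>CG")
  unname(map[key])
}

#' Mutation-rate model
#'
#' @param mu_per_site_per_gen Base-substitution rate per site per
#'   generation (default 7e-9, the Arabidopsis estimate used as a proxy
#'   for maize).
#' @param genome_size_bp Genome size in bp (default 2.3e9).
#' @return A `mutation_rate_model` list.
#' @export
mutation_rate_model <- function(mu_per_site_per_gen = 7e-9,
                                genome_size_bp = 2.3e9) {
  stopifnot(mu_per_site_per_gen > 0, genome_size_bp > 0)
  structure(list(mu = mu_per_site_per_gen, genome_bp = genome_size_bp),
            class = "mutation_rate_model")
}

#' Expected mutations per generation
#' @param model A [mutation_rate_model()].
#' @return mu x genome size, unrounded (16.1 for the defaults).
#' @export
mutations_per_generation <- function(model = mutation_rate_model()) {
  model$mu * model$genome_bp
}

#' Generations separating two genomes from a de novo count
#'
#' @param n_denovo Non-negative count of de novo SNPs.
#' @param model A [mutation_rate_model()].
#' @return `n_denovo / (mu x genome size)` rounded to the nearest integer
#'   (half away from zero).
#' @export
generations_removed <- function(n_denovo, model = mutation_rate_model()) {
  stopifnot(all(n_denovo >= 0))
  as.integer(round_half_away(n_denovo / mutations_per_generation(model)))
}
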