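# Differential-expression table filtering and genomic windowing. DE testing
# itself is upstream (the table is input); here the DE set is thresholded
# and summarized along the genome and against the introgression intervals.

#' Read a differential-expression gene table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open locus), `fpkm_a`, `fpkm_b`, optional `log2fc`,
#'   `q_value`.
#' @return data.frame of DE-gene records.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "fpkm_a", "fpkm_b", "q_value")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  de
}

#' Filter a DE table to significantly, strongly changed genes
#'
#' Retains records with `q_value <= max_q` and absolute log2 fold change at
#' least `min_abs_lfc`. A missing `log2fc` column (or NA entries) is
#' computed from the group expression values as
#' `log2((fpkm_a + eps) / (fpkm_b + eps))` with `eps = 1e-3`.
#'
#' @param de data.frame from [read_de_table()].
#' @param max_q Corrected p-value ceiling (default 0.05).
#' @param min_abs_lfc Minimum |log2 fold change| (default 2).
#' @param eps Pseudo-expression added before the ratio (default 1e-3).
#' @return The retained subset, with a populated `log2fc` column.
#' @export
filter_de <- function(de, max_q = 0.05, min_abs_lfc = 2, eps = 1e-3) {
  lfc <- if (!is.null(de$log2fc)) de$log2fc else rep(NA_real_, nrow(de))
  need <- is.na(lfc)
  lfc[need] <- log2((de$fpkm_a[need] + eps) / (de$fpkm_b[need] + eps))
  de$log2fc <- lfc
  keep <- !is.na(de$q_value) & de$q_value <= max_q & abs(lfc) >= min_abs_lfc
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count DE genes in non-overlapping genomic windows
#'
#' Each gene is assigned to the window containing its locus start, so a
#' gene spanning a window boundary counts exactly once and window totals
#' conserve the DE-set size.
#'
#' @param de_set data.frame with `chrom` and `start`.
#' @param layout A `genome_layout`.
#' @param width Window width in bp (default 1e7, i.e. 10 Mb).
#' @return A `bin_grid`-style data.frame (`chrom`, `bin`, `start`,
#'   `count`).
#' @export
de_window_counts <- function(de_set, layout, width = 1e7) {
  bin_snp_counts(data.frame(chrom = de_set$chrom, pos = de_set$start,
                            stringsAsFactors = FALSE),
                 layout, width)
}

#' Partition DE genes by introgression-interval overlap
#'
#' A gene is "inside" when its locus overlaps any interval by at least one
#' bp; inside + outside = total.
#'
#' @param de_set data.frame with `chrom`, `start`, `end`.
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return List with `n_inside`, `n_outside`, and logical `inside`.
#' @export
de_interval_overlap <- function(de_set, intervals) {
  if (!nrow(de_set)) {
    return(list(n_inside = 0L, n_outside = 0L, inside = logical(0)))
  }
  if (!nrow(intervals)) {
    return(list(n_inside = 0L, n_outside = nrow(de_set),
                inside = rep(FALSE, nrow(de_set))))
  }
  q <- GenomicRanges::GRanges(de_set$chrom,
                              IRanges::IRanges(start = de_set$start + 1,
                                               end = de_set$end))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(start = intervals$start + 1,
                                               end = intervals$end))
  inside <- GenomicRanges::countOverlaps(q, s) > 0
  list(n_inside = sum(inside), n_outside = sum(!inside), inside = inside)
}
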