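# Windowed SNP-density scan: count SNPs in non-overlapping fixed-width bins
# (100 kb by default), call introgression intervals as runs of bins whose
# count exceeds a threshold, merging across short runs of sub-threshold
# bins, and summarize physical and genetic interval metrics.

#' Scan parameters
#'
#' @param min_snps_per_bin Strictly-greater-than threshold: a bin qualifies
#'   when its SNP count is `> min_snps_per_bin` (default 2, i.e. bins with
#'   more than two SNPs).
#' @param max_gap_bins Qualifying bins on the same chromosome separated by
#'   at most this many non-qualifying bins are merged into one interval
#'   (default 5).
#' @param cm_per_mb Local recombination rate used to convert physical span
#'   to genetic length (default 3 cM/Mb, typical of subtelomeric maize).
#' @return A `scan_params` list.
#' @export
scan_params <- function(min_snps_per_bin = 2, max_gap_bins = 5,
                        cm_per_mb = 3.0) {
  stopifnot(min_snps_per_bin >= 0, max_gap_bins >= 0, cm_per_mb >= 0)
  structure(list(min_snps_per_bin = min_snps_per_bin,
                 max_gap_bins = max_gap_bins, cm_per_mb = cm_per_mb),
            class = "scan_params")
}

#' Count SNPs in non-overlapping genomic bins
#'
#' Bin `i` of a chromosome covers `[i * width, (i + 1) * width)` in 0-based
#' coordinates; every SNP increments exactly one bin, so the grid total
#' equals the number of input SNPs.
#'
#' @param snps data.frame with `chrom` and `pos` (0-based), e.g. one line's
#'   private set from [classify_private()].
#' @param layout A `genome_layout`.
#' @param width Bin width in bp (default 100000).
#' @return A `bin_grid`: data.frame with `chrom`, `bin` (0-based index),
#'   `start`, `count`, covering every bin of every chromosome; attributes
#'   `width` and `layout`.
#' @export
bin_snp_counts <- function(snps, layout, width = 100000) {
  stopifnot(width > 0)
  if (nrow(snps)) {
    len <- chrom_length(layout, snps$chrom)
    if (any(snps$pos < 0) || any(snps$pos >= len)) {
      stop("SNP position outside chromosome bounds")
    }
  }
  grids <- lapply(seq_len(nrow(layout)), function(i) {
    nb <- ceiling(layout$length[i] / width)
    counts <- integer(nb)
    sel <- snps$chrom == layout$name[i]
    if (any(sel)) {
      idx <- floor(snps$pos[sel] / width)
      tab <- table(idx)
      counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    data.frame(chrom = layout$name[i], bin = seq_len(nb) - 1L,
               start = (seq_len(nb) - 1) * width, count = counts,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  attr(grid, "width") <- width
  attr(grid, "layout") <- layout
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Call introgression intervals from a bin grid
#'
#' Bins with count strictly greater than `min_snps_per_bin` qualify.
#' Qualifying bins on the same chromosome separated by at most
#' `max_gap_bins` non-qualifying bins are merged; an interval spans from
#' the first qualifying bin's start to the last qualifying bin's end
#' (bin-aligned bounds). `snp_count` sums all bins inside the interval,
#' including interior gap bins.
#'
#' @param grid A `bin_grid` from [bin_snp_counts()].
#' @param params A [scan_params()] object.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   bin-aligned), `snp_count`, `bin_count` (bins spanned), `n_qual_bins`,
#'   `max_bin_count`, sorted in genome order.
#' @export
call_intervals <- function(grid, params = scan_params()) {
  width <- attr(grid, "width")
  layout <- attr(grid, "layout")
  out <- list()
  for (chr in layout$name) {
    g <- grid[grid$chrom == chr, , drop = FALSE]
    qual <- which(g$count > params$min_snps_per_bin)
    if (!length(qual)) next
    run_id <- cumsum(c(1L, diff(qual) - 1L > params$max_gap_bins))
    for (r in split(qual, run_id)) {
      first <- min(r); last <- max(r)
      inside <- g$count[first:last]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = g$start[first],
        end = g$start[last] + width,
        snp_count = sum(inside),
        bin_count = last - first + 1L,
        n_qual_bins = length(r),
        max_bin_count = max(inside),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), snp_count = integer(0),
                      bin_count = integer(0), n_qual_bins = integer(0),
                      max_bin_count = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(layout, res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Physical and genetic summary metrics for called intervals
#'
#' @param intervals data.frame from [call_intervals()] (or any interval set
#'   with `chrom`, `start`, `end` and optionally `snp_count`).
#' @param layout A `genome_layout`; genome size is its total length unless
#'   `genome_bp` overrides it.
#' @param params A [scan_params()] supplying `cm_per_mb`.
#' @param genome_bp Optional explicit genome size in bp.
#' @param total_snps Denominator for the per-interval SNP shares: the
#'   line's complete private-SNP count (intervals typically do not hold
#'   every SNP). Defaults to the sum of the interval counts.
#' @return List with `per_interval` (adds `span_bp`, `span_mb`, `label`
#'   like `"chr10: 142.3-145.3 Mb"`, and `share_pct` when `snp_count`
#'   present), `combined_bp`, `combined_mb`, `fraction_of_genome`,
#'   `pct_of_genome` (one decimal), `genetic_length_cm`.
#' @export
interval_metrics <- function(intervals, layout, params = scan_params(),
                             genome_bp = NULL, total_snps = NULL) {
  if (nrow(intervals) > 1) {
    ord <- order(chrom_rank(layout, intervals$chrom), intervals$start)
    iv <- intervals[ord, , drop = FALSE]
    same <- iv$chrom[-nrow(iv)] == iv$chrom[-1]
    if (any(same & iv$end[-nrow(iv)] > iv$start[-1])) {
      stop("overlapping intervals: interval assembly is inconsistent")
    }
    intervals <- iv
  }
  if (is.null(genome_bp)) genome_bp <- genome_size(layout)
  span <- intervals$end - intervals$start
  per <- intervals
  per$span_bp <- span
  per$span_mb <- span / 1e6
  per$label <- sprintf("%s: %s-%s Mb", per$chrom,
                       format_mb(per$start), format_mb(per$end))
  if (!is.null(per$snp_count) && sum(per$snp_count) > 0) {
    if (is.null(total_snps)) total_snps <- sum(per$snp_count)
    per$share_pct <- pct1(per$snp_count, total_snps)
  }
  combined <- sum(span)
  list(per_interval = per,
       combined_bp = combined,
       combined_mb = combined / 1e6,
       fraction_of_genome = combined / genome_bp,
       pct_of_genome = pct1(combined, genome_bp),
       genetic_length_cm = combined / 1e6 * params$cm_per_mb)
}
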