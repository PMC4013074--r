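# Exon-annotation overlap: fraction of SNPs falling in annotated exons.

#' Read an exon set from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED is taken natively. From GFF3 only
#' features of type `exon` are used. Exons may overlap each other;
#' duplicated records never change overlap results.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `id` (gene/transcript tag when available).
#' @export
read_exons <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    id <- if (!is.null(gr$ID)) as.character(gr$ID)
          else if (!is.null(gr$Parent)) vapply(gr$Parent, function(p)
            if (length(p)) as.character(p[1]) else NA_character_, character(1))
          else rep(NA_character_, length(gr))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               id = id, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), id = character(0),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t")
    data.frame(chrom = vapply(parts, `[`, "", 1),
               start = as.numeric(vapply(parts, `[`, "", 2)),
               end = as.numeric(vapply(parts, `[`, "", 3)),
               id = vapply(parts, function(p)
                 if (length(p) >= 4) p[4] else NA_character_, ""),
               stringsAsFactors = FALSE)
  }
}

#' Exonic SNP count and fraction
#'
#' A SNP is exonic iff its position lies inside at least one exon interval;
#' overlapping or duplicated exons count a SNP once.
#'
#' @param snps data.frame with `chrom`, `pos` (0-based).
#' @param exons data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_exons()].
#' @return List with `n_exonic`, `n_total`, `fraction_pct` (one decimal;
#'   `NA` for an empty SNP set) and logical vector `exonic`.
#' @export
exonic_fraction <- function(snps, exons) {
  if (!nrow(snps)) {
    return(list(n_exonic = 0L, n_total = 0L, fraction_pct = NA_real_,
                exonic = logical(0)))
  }
  hit <- snps_in_intervals(snps, exons)
  list(n_exonic = sum(hit), n_total = nrow(snps),
       fraction_pct = pct1(sum(hit), nrow(snps)), exonic = hit)
}
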