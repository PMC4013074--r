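# Core coordinate model and file readers/writers.
#
# All positions are 0-based half-open internally; VCF POS is converted on
# read (pos - 1) and back on write. Reports render coordinates as Mb to one
# decimal, which is lossless for bin-aligned (multiple-of-100-kb) bounds.

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Read a genome layout table
#'
#' A genome layout is the ordered set of chromosome names and lengths. The
#' order given in the file is preserved and used for all downstream sorting,
#' binning and reporting.
#'
#' @param path Path to a tab-separated file with columns `name` and `length`
#'   (header optional; two-column files without a header are accepted).
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `name` (character) and `length` (integer bp), plus attribute
#'   `total_bp`.
#' @export
read_genome_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  if (identical(tolower(raw$name[1]), "name")) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) stop("layout file is empty: ", path)
  genome_layout(raw$name, as.numeric(raw$length))
}

#' Construct a genome layout from vectors
#'
#' @param names Chromosome names, unique, in reporting order.
#' @param lengths Chromosome lengths in bp, all positive.
#' @return A `genome_layout` object.
#' @export
genome_layout <- function(names, lengths) {
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) stop("names and lengths differ in length")
  if (anyDuplicated(names)) stop("duplicate chromosome names in layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(name = as.character(names), length = lengths,
                    stringsAsFactors = FALSE)
  attr(out, "total_bp") <- sum(lengths)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Total genome size of a layout
#' @param layout A `genome_layout`.
#' @return Total length in bp.
#' @export
genome_size <- function(layout) sum(layout$length)

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$name)
  if (anyNA(i)) stop("chromosome not in layout: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

chrom_rank <- function(layout, chrom) match(chrom, layout$name)

#' Read a VCF into a site table
#'
#' Parses a VCF 4.x file into the rectangular site-by-sample structure used
#' by the filtering and scanning steps. Only biallelic SNP records are
#' retained: indels and multi-allelic records are dropped and counted.
#' Genotype strings are collapsed to a four-class code (`hom_ref`, `het`,
#' `hom_alt`, `missing`); phased (`|`) and unphased (`/`) separators are
#' treated identically. Missing per-sample DP or GQ fields become 0, which
#' guarantees such calls fail any positive threshold rather than passing
#' silently.
#'
#' @param path Path to a (plain-text) VCF file.
#' @param sample_subset Optional character vector restricting and ordering
#'   the samples; an unknown name is an error listing the available names.
#' @return A `site_table`: list with `sites` (data.frame `chrom`, `pos`
#'   0-based, `ref`, `alt`, `qual`), `samples`, matrices `gt` (character,
#'   4-class), `dp` (numeric), `gq` (numeric), and `dropped` (named counts
#'   of excluded records).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) {
    samples <- colnames(v@gt)[-1]
    return(empty_site_table(if (is.null(sample_subset)) samples else sample_subset))
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_snp <- !multi & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  dropped <- c(multiallelic = sum(multi),
               indel_or_nonsnp = sum(!is_snp & !multi))
  keep <- which(is_snp)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  samples <- colnames(gt_raw)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss)) {
      stop("sample(s) not in VCF: ", paste(miss, collapse = ", "),
           "; available: ", paste(samples, collapse = ", "))
    }
    samples <- sample_subset
  }
  as_mat <- function(m) {
    m <- m[keep, samples, drop = FALSE]
    matrix(m, nrow = length(keep), ncol = length(samples),
           dimnames = list(NULL, samples))
  }
  gt_m <- as_mat(gt_raw)
  u <- unique(as.vector(gt_m))
  cls <- vapply(u, classify_gt_string, character(1))
  gt <- matrix(cls[match(gt_m, u)], nrow = nrow(gt_m),
               dimnames = dimnames(gt_m))
  dp <- as_mat(dp_raw); dp[is.na(dp)] <- 0
  gq <- as_mat(gq_raw); gq[is.na(gq)] <- 0

  qual <- suppressWarnings(as.numeric(fix$QUAL[keep]))
  qual[is.na(qual)] <- 0
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.numeric(fix$POS[keep]) - 1,
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      qual = qual, stringsAsFactors = FALSE)

  st <- site_table(sites, samples, gt, dp, gq, dropped = dropped)
  st
}

classify_gt_string <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return("missing")
  al <- strsplit(g, "[/|]")[[1]]
  if (any(al == ".")) return("missing")
  al <- suppressWarnings(as.integer(al))
  if (anyNA(al)) return("missing")
  if (all(al == 0)) return("hom_ref")
  if (all(al == 1)) return("hom_alt")
  "het"
}

#' Construct a site table
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `qual`.
#' @param samples Ordered sample names.
#' @param gt,dp,gq Site-by-sample matrices of genotype class, depth and
#'   genotype quality.
#' @param dropped Optional named counts of records excluded at read time.
#' @return A `site_table` object, sites sorted by (chrom, pos) in input
#'   chromosome order, duplicate positions removed (first kept, with a
#'   warning).
#' @export
site_table <- function(sites, samples, gt, dp, gq, dropped = c()) {
  stopifnot(nrow(sites) == nrow(gt), ncol(gt) == length(samples))
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    warning("duplicate (chrom,pos) records: keeping first of each")
    keep <- !duplicated(key)
    sites <- sites[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    dp <- dp[keep, , drop = FALSE]
    gq <- gq[keep, , drop = FALSE]
  }
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 samples = samples,
                 gt = gt[ord, , drop = FALSE],
                 dp = dp[ord, , drop = FALSE],
                 gq = gq[ord, , drop = FALSE],
                 dropped = dropped),
            class = "site_table")
}

empty_site_table <- function(samples) {
  m <- matrix(character(0), nrow = 0, ncol = length(samples),
              dimnames = list(NULL, samples))
  structure(list(sites = data.frame(chrom = character(0), pos = numeric(0),
                                    ref = character(0), alt = character(0),
                                    qual = numeric(0), stringsAsFactors = FALSE),
                 samples = samples, gt = m,
                 dp = matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples)),
                 gq = matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples)),
                 dropped = c()),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  if (length(x$dropped)) {
    cat("dropped at read:",
        paste(sprintf("%s=%d", names(x$dropped), x$dropped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of sites in a site table
#' @param st A `site_table`.
#' @return Integer site count.
#' @export
n_sites <- function(st) nrow(st$sites)

#' Write genomic intervals as BED3
#'
#' Intervals are written 0-based half-open and sorted by layout order when a
#' layout is given (otherwise by first appearance). An empty interval set
#' produces a file holding only the header comment, so that a round trip
#' through [read_intervals_bed()] recovers an empty set.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @param layout Optional `genome_layout` giving chromosome order.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
    stop("invalid interval bounds")
  }
  if (!is.null(layout)) {
    intervals <- intervals[order(chrom_rank(layout, intervals$chrom),
                                 intervals$start), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend", con)
  if (nrow(intervals)) {
    writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end)),
               con)
  }
  invisible(path)
}

#' Read a BED3 file of intervals
#' @param path Path to a BED file (comment lines ignored).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(chrom = parts[, 1], start = as.numeric(parts[, 2]),
             end = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
}

#' Write an analysis report as JSON
#' @param summary Named list of summary statistics keyed by stage.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Render a position in Mb to one decimal
#'
#' Lossless for bin-aligned positions (multiples of 100 kb): `parse_mb()`
#' inverts it exactly.
#'
#' @param pos Position(s) in bp.
#' @return Character vector like `"142.3"`.
#' @export
format_mb <- function(pos) sprintf("%.1f", pos / 1e6)

#' Parse an Mb rendering back to bp
#' @param x Character vector like `"142.3"`.
#' @return Numeric positions in bp.
#' @export
parse_mb <- function(x) round(as.numeric(x) * 1e6)

# Round half away from zero, the convention used for all reported decimals.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage rendered to one decimal
#' @param num,den Numerator and denominator.
#' @return Numeric percent rounded half away from zero to one decimal;
#'   `NA` when `den` is 0.
#' @export
pct1 <- function(num, den) {
  if (length(den) == 1 && den == 0) return(NA_real_)
  round_half_away(100 * num / den, 1)
}
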