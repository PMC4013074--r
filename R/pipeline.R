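# End-to-end orchestration: filter -> scan -> panel/de novo -> annotation
# -> RNA-seq concordance -> DE windows, producing one machine-readable
# report. Each stage calls the same exported function a direct invocation
# would, so the report never contains orchestration-only logic.

#' Run the full analysis pipeline
#'
#' @param inputs Named list of file paths: `layout`, `wgs_vcf`, `panel`,
#'   and optionally `rna_vcf`, `exons`, `de_table`. Missing optional
#'   inputs skip their stage. `sample_a`/`sample_b` name the two WGS
#'   samples (defaults `"A"`, `"B"`); `group_a`/`group_b` name the RNA
#'   replicate samples (defaults: samples starting with A / with B).
#' @param thresholds A [filter_thresholds()].
#' @param params A [scan_params()].
#' @param model A [mutation_rate_model()]; its genome size is used for the
#'   generation estimates, while interval metrics use the layout's actual
#'   size.
#' @param min_rna_depth Depth required for an RNA genotype call
#'   (default 10).
#' @param report_path Optional path; when given the report is written as
#'   JSON via [write_report()].
#' @return The report: a nested list with elements `filter`
#'   (`total_discriminating`, `private_counts`), `scan` (`intervals`,
#'   `interval_shares`, `combined_mb`, `pct_genome`, `genetic_length_cm`),
#'   `panel` (`panel_fractions`), `denovo` (`denovo_counts`, `spectrum`,
#'   `mutations_per_gen`, `generations`), `annotation`
#'   (`exonic_fraction`), `concordance`, `de` (`de_counts`), plus
#'   `objects` (the underlying R objects for programmatic use).
#' @export
run_pipeline <- function(inputs, thresholds = filter_thresholds(),
                         params = scan_params(),
                         model = mutation_rate_model(),
                         min_rna_depth = 10, report_path = NULL) {
  need <- c("layout", "wgs_vcf", "panel")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing required input(s): ", paste(miss, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  layout <- stage("layout", read_genome_layout(inputs$layout))
  sample_a <- inputs$sample_a %||% "A"
  sample_b <- inputs$sample_b %||% "B"

  ## stage: filter
  wgs <- stage("filter", read_vcf(inputs$wgs_vcf))
  priv <- stage("filter", classify_private(wgs, sample_a, sample_b, thresholds))
  message(sprintf("[filter] %d sites read, %d retained (%s: %d, %s: %d)",
                  priv$n_input, priv$n_retained,
                  sample_a, priv$counts[[sample_a]],
                  sample_b, priv$counts[[sample_b]]))

  ## stage: scan (on the set private to sample B, the introgression carrier)
  snps_b <- priv$snps[priv$snps$private_to == sample_b, , drop = FALSE]
  snps_a <- priv$snps[priv$snps$private_to == sample_a, , drop = FALSE]
  grid <- stage("scan", bin_snp_counts(snps_b, layout))
  intervals <- stage("scan", call_intervals(grid, params))
  metrics <- stage("scan", interval_metrics(intervals, layout, params,
                                            total_snps = nrow(snps_b)))
  message(sprintf("[scan] %d interval(s), combined %.1f Mb",
                  nrow(intervals), metrics$combined_mb))

  ## stage: classify (panel membership + de novo)
  panel <- stage("classify", read_panel(inputs$panel))
  pm_a <- stage("classify", panel_membership(snps_a, panel))
  pm_b <- stage("classify", panel_membership(snps_b, panel))
  dn_a <- stage("classify", derive_denovo(snps_a, panel, intervals))
  dn_b <- stage("classify", derive_denovo(snps_b, panel, intervals))
  spectrum <- stage("classify", mutation_spectrum(rbind(dn_a, dn_b)))
  mpg <- mutations_per_generation(model)
  gens <- c(a = generations_removed(nrow(dn_a), model),
            b = generations_removed(nrow(dn_b), model))
  message(sprintf("[classify] de novo %d/%d; ~%d mutations/generation",
                  nrow(dn_a), nrow(dn_b), round(mpg)))

  ## stage: annotate
  annot <- NULL
  if (!is.null(inputs$exons)) {
    exons <- stage("annotate", read_exons(inputs$exons))
    annot <- stage("annotate", exonic_fraction(priv$snps, exons))
    message(sprintf("[annotate] %d/%d SNPs exonic (%.1f%%)",
                    annot$n_exonic, annot$n_total, annot$fraction_pct))
  }

  ## stage: concord
  conc <- NULL
  if (!is.null(inputs$rna_vcf)) {
    rna <- stage("concord", read_vcf(inputs$rna_vcf))
    group_a <- inputs$group_a %||% grep("^A", rna$samples, value = TRUE)
    group_b <- inputs$group_b %||% grep("^B", rna$samples, value = TRUE)
    calls <- stage("concord",
                   genotype_at_sites(rna, snps_b, min_depth = min_rna_depth))
    rep_b <- stage("concord",
                   concordance_report(calls[, group_b, drop = FALSE], snps_b))
    rep_a <- stage("concord",
                   concordance_report(calls[, group_a, drop = FALSE], snps_b,
                                      expected = "hom_ref"))
    disc <- stage("concord", group_discriminating(rna, group_a, group_b,
                                                  thresholds))
    conc <- list(group_b = rep_b, group_a = rep_a,
                 n_group_discriminating = nrow(disc),
                 group_discriminating = disc)
    message(sprintf("[concord] %d typed in group B, %d%% matching WGS",
                    rep_b$n_typed, rep_b$pct_match))
  }

  ## stage: dewindows
  de <- NULL
  if (!is.null(inputs$de_table)) {
    de_tab <- stage("dewindows", read_de_table(inputs$de_table))
    de_set <- stage("dewindows", filter_de(de_tab))
    ov <- stage("dewindows", de_interval_overlap(de_set, intervals))
    de <- list(n_input = nrow(de_tab), n_de = nrow(de_set),
               n_in_intervals = ov$n_inside,
               n_outside_intervals = ov$n_outside,
               windows = de_window_counts(de_set, layout))
    message(sprintf("[dewindows] %d DE genes, %d in intervals",
                    de$n_de, de$n_in_intervals))
  }

  report <- list(
    schema_version = "1.0",
    filter = list(total_discriminating = priv$n_retained,
                  private_counts = as.list(priv$counts),
                  n_input_sites = priv$n_input,
                  dropped_at_read = as.list(wgs$dropped)),
    scan = list(intervals = metrics$per_interval[, c("chrom", "start", "end",
                                                     "snp_count", "label")],
                interval_shares = metrics$per_interval$share_pct,
                combined_mb = metrics$combined_mb,
                pct_genome = metrics$pct_of_genome,
                genetic_length_cm = metrics$genetic_length_cm),
    panel = list(panel_fractions = list(a = pm_a$fraction_pct,
                                        b = pm_b$fraction_pct)),
    denovo = list(denovo_counts = list(a = nrow(dn_a), b = nrow(dn_b)),
                  spectrum = as.list(spectrum),
                  mutations_per_gen = mpg,
                  generations = as.list(gens)),
    annotation = if (!is.null(annot))
      list(exonic_fraction = annot$fraction_pct, n_exonic = annot$n_exonic),
    concordance = if (!is.null(conc))
      list(n_typed_b = conc$group_b$n_typed,
           pct_match_b = conc$group_b$pct_match,
           n_other_allele_b = conc$group_b$n_other_allele,
           n_het_b = conc$group_b$n_het,
           n_typed_a = conc$group_a$n_typed,
           pct_match_a = conc$group_a$pct_match,
           n_group_discriminating = conc$n_group_discriminating),
    de = if (!is.null(de))
      list(de_counts = list(total = de$n_de,
                            in_intervals = de$n_in_intervals,
                            outside = de$n_outside_intervals)))
  report$objects <- list(private = priv, grid = grid, intervals = intervals,
                         metrics = metrics, denovo = list(a = dn_a, b = dn_b),
                         concordance = conc, de = de)
  if (!is.null(report_path)) {
    write_report(report[setdiff(names(report), "objects")], report_path)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
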