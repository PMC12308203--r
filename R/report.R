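#' One-shot descriptive report for an annotated mitogenome
#'
#' Runs every descriptive stage on one annotated genome and writes the
#' classical report tables to an output directory: `composition.tsv`
#' (composition by partition), `geometry.tsv` (the annotation report with
#' the signed intergenic column) plus `geometry_summary.tsv`,
#' `codon_usage.tsv` (per-codon counts and RSCU), `codon_metrics.tsv`
#' (ENC, CBI, GC, GC3), `trna_classes.tsv`, and `gene_order.txt`. The
#' effective configuration is echoed to `run_config.tsv` for provenance.
#' Outputs are deterministic: the same inputs produce byte-identical
#' files.
#'
#' @param record A `sequence_record` (the genome).
#' @param annotation A `mito_annotation`.
#' @param out_dir Output directory (created if needed).
#' @param code A [mito_genetic_code()].
#' @param control_region_min Control-region threshold (bp) for the
#'   geometry stage.
#' @return Invisibly, a named list of the computed objects.
#' @export
run_report <- function(record, annotation, out_dir,
                       code = mito_genetic_code(),
                       control_region_min = 1000) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- record$residues
  tsv <- function(x, file) {
    write.table(x, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  comp <- composition_table(annotation, res)
  comp_out <- comp
  for (col in c("pct_t", "pct_c", "pct_a", "pct_g", "pct_at")) {
    comp_out[[col]] <- round_half_up(comp_out[[col]], 1)
  }
  comp_out$at_skew <- round_skew(comp_out$at_skew)
  comp_out$gc_skew <- round_skew(comp_out$gc_skew)
  tsv(comp_out, "composition.tsv")

  geom <- compute_geometry(annotation, control_region_min)
  tsv(write_annotation_report(annotation, geom), "geometry.tsv")
  s <- geom$summary
  tsv(data.frame(
    quantity = c("n_overlaps", "overlap_min", "overlap_max", "n_spacers",
                 "spacer_min", "spacer_max", "n_control_regions",
                 "control_region_lengths", "closes_circle"),
    value = c(s$n_overlaps, s$overlap_range, s$n_spacers, s$spacer_range,
              s$n_control_regions,
              paste(s$control_region_lengths, collapse = ","),
              geom$closes_circle)), "geometry_summary.tsv")

  pcg <- annotation$features$gene[annotation$features$feature_class == "PCG"]
  out <- list(composition = comp, geometry = geom)
  if (length(pcg) > 0) {
    cds <- vapply(pcg, function(g) feature_sequence(annotation, res, g), "")
    counts <- count_codons(cds, code = code, genes = pcg)
    ru <- rscu(counts)
    tsv(ru[, c("amino_acid", "codon", "family_size", "count",
               "rscu_rounded")], "codon_usage.tsv")
    metrics <- codon_bias_metrics(counts)
    tsv(cbind(metrics, n_codons = sum(counts)), "codon_metrics.tsv")
    out$codon_usage <- ru
    out$codon_metrics <- metrics
  }

  trna <- classify_trnas(annotation, res)
  tsv(trna$table, "trna_classes.tsv")
  ord <- extract_gene_order(annotation, taxon = record$id)
  writeLines(paste(record$id, paste(format_signed(ord), collapse = ",")),
             file.path(out_dir, "gene_order.txt"))
  out$trna <- trna
  out$gene_order <- ord

  tsv(data.frame(
    parameter = c("genome", "genome_length", "genetic_code",
                  "control_region_min", "n_features"),
    value = c(record$id, annotation$genome_length, code$id,
              control_region_min, nrow(annotation$features))),
    "run_config.tsv")
  invisible(out)
}
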