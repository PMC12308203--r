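#' Strand compositional skews
#'
#' AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C), the standard
#' strand-asymmetry measures of mitogenomics. Inputs may be percentages or
#' raw counts; only the ratio matters. A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param a,t,g,c Percentages (or counts) of the respective bases.
#' @return Signed skew in `[-1, 1]`, unrounded; use [round_skew()] for the
#'   3-decimal reporting convention.
#' @examples
#' at_skew(41.2, 47.8)   # -0.074 once rounded
#' @export
at_skew <- function(a, t) {
  ifelse(a + t == 0, NA_real_, (a - t) / (a + t))
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  ifelse(g + c == 0, NA_real_, (g - c) / (g + c))
}

#' @rdname at_skew
#' @param x Skew value.
#' @export
round_skew <- function(x) round_half_up(x, 3)

#' Nucleotide composition of a sequence
#'
#' Percentages of A/T/G/C (N and other ambiguity codes excluded from the
#' denominator) plus A+T content and the two skews, i.e. one row of the
#' classical composition-by-partition table.
#'
#' @param residues DNA string.
#' @param label Partition label carried into the profile.
#' @return A `composition_profile`: one-row data.frame with columns
#'   `partition`, `pct_t`, `pct_c`, `pct_a`, `pct_g`, `pct_at`, `at_skew`,
#'   `gc_skew` (percentages and skews unrounded).
#' @export
base_composition <- function(residues, label = "sequence") {
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("empty sequence")
  n <- vapply(c("A", "C", "G", "T"),
              function(b) lengths(regmatches(residues,
                                             gregexpr(b, residues, fixed = TRUE))),
              numeric(1))
  tot <- sum(n)
  if (tot == 0) stop("sequence has no unambiguous A/C/G/T residues")
  pct <- 100 * n / tot
  out <- data.frame(partition = label,
                    pct_t = pct[["T"]], pct_c = pct[["C"]],
                    pct_a = pct[["A"]], pct_g = pct[["G"]],
                    pct_at = pct[["A"]] + pct[["T"]],
                    at_skew = at_skew(n[["A"]], n[["T"]]),
                    gc_skew = gc_skew(n[["G"]], n[["C"]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_profile", class(out))
  out
}

#' Composition by codon position across protein-coding genes
#'
#' Pools the protein-coding genes selected by `strand_filter`, reads each on
#' its sense strand (N-strand genes reverse-complemented), and computes one
#' composition profile per codon position. Note the partition semantics:
#' codon positions are defined on each gene's own coding strand, grouped by
#' which genome strand encodes the gene - this is what produces the
#' characteristic GC-skew sign flip between J- and N-strand partitions.
#'
#' @param annotation A `mito_annotation`.
#' @param residues Genome sequence.
#' @param strand_filter `"all"`, `"J"` or `"N"`.
#' @param label_prefix Prefix for the partition labels.
#' @return data.frame of three `composition_profile` rows (positions 1-3).
#' @export
codon_position_composition <- function(annotation, residues,
                                       strand_filter = c("all", "J", "N"),
                                       label_prefix = "PCG") {
  strand_filter <- match.arg(strand_filter)
  f <- annotation$features[annotation$features$feature_class == "PCG", ,
                           drop = FALSE]
  if (strand_filter != "all") f <- f[f$strand == strand_filter, , drop = FALSE]
  if (nrow(f) == 0) stop("no protein-coding genes in selection")
  pos_seq <- c("1" = "", "2" = "", "3" = "")
  for (g in f$gene) {
    cds <- feature_sequence(annotation, residues, g)
    if (nchar(cds) %% 3 != 0) {
      stop("PCG length not divisible by 3: ", g, " (", nchar(cds), " bp)")
    }
    chars <- strsplit(cds, "")[[1]]
    for (p in 1:3) {
      pos_seq[[p]] <- paste0(pos_seq[[p]],
                             paste0(chars[seq(p, length(chars), 3)],
                                    collapse = ""))
    }
  }
  out <- do.call(rbind, lapply(1:3, function(p) {
    base_composition(pos_seq[[p]],
                     label = sprintf("%s codon position %d", label_prefix, p))
  }))
  out
}

#' Gene length on a circular genome
#'
#' `end - start + 1` for ordinary features; features flagged as wrapping the
#' origin have length `genome_length - start + 1 + end`.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param genome_length Genome length in bp.
#' @param wraps_origin Does the feature run through the origin?
#' @return Length in bp.
#' @export
gene_length <- function(start, end, genome_length, wraps_origin = FALSE) {
  ifelse(wraps_origin, genome_length - start + 1 + end, end - start + 1)
}

#' Gene geometry: lengths, overlaps, spacers, control regions
#'
#' Walks the circular feature order (including the wrap-around junction from
#' the last feature back to the first) and computes the signed spacer at
#' every junction: `next.start - prev.end - 1`, so negative values are
#' overlaps, 0 abutting genes, and positive values intergenic spacers.
#' Spacers of at least `control_region_min` bp are classified as control
#' regions and excluded from the spacer counts and ranges. The default
#' threshold of 1000 bp sits far above real intergenic spacers (tens of bp)
#' and far below real control regions (kilobases) in scale-insect
#' mitogenomes.
#'
#' @param annotation A circular `mito_annotation`.
#' @param control_region_min Minimum spacer length (bp) classified as a
#'   control region.
#' @return A `geometry_report`: list with `gene_lengths` (named vector),
#'   `spacers` (data.frame upstream/downstream/length/class), `summary`
#'   (counts and ranges), and `closes_circle` (exact bp accounting check).
#' @export
compute_geometry <- function(annotation, control_region_min = 1000) {
  f <- annotation$features
  if (nrow(f) == 0) stop("annotation has no features")
  L <- annotation$genome_length
  lens <- stats::setNames(
    gene_length(f$start, f$end, L, f$wraps_origin), f$gene)
  n <- nrow(f)
  nxt <- c(seq_len(n)[-1], 1L)
  raw <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    sp <- f$start[j] - f$end[i] - 1L
    if (j == 1L && annotation$topology == "circular" && !f$wraps_origin[i]) {
      sp <- f$start[j] + L - f$end[i] - 1L
    }
    raw[i] <- sp
  }
  cls <- ifelse(raw < 0, "overlap",
         ifelse(raw == 0, "abutting",
         ifelse(raw >= control_region_min, "control_region", "spacer")))
  spacers <- data.frame(upstream = f$gene, downstream = f$gene[nxt],
                        length = raw, class = cls, stringsAsFactors = FALSE)
  ov <- -raw[cls == "overlap"]
  sp <- raw[cls == "spacer"]
  cr <- raw[cls == "control_region"]
  summary <- list(
    n_overlaps = length(ov),
    overlap_range = if (length(ov)) range(ov) else c(NA_integer_, NA_integer_),
    n_spacers = length(sp),
    spacer_range = if (length(sp)) range(sp) else c(NA_integer_, NA_integer_),
    n_control_regions = length(cr),
    control_region_lengths = cr,
    n_abutting = sum(cls == "abutting"))
  # circle accounting: gene bp (overlapped stretches once) + gaps = L.
  # Sum of lengths + all signed spacers counts each overlapped stretch once
  # for a circular order with pairwise-nested-free overlaps.
  closes <- (annotation$topology != "circular") ||
    (sum(lens) + sum(raw) == L)
  structure(list(gene_lengths = lens, spacers = spacers, summary = summary,
                 closes_circle = closes,
                 control_region_min = control_region_min),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  s <- x$summary
  cat("<geometry_report> ", length(x$gene_lengths), " genes\n", sep = "")
  cat(sprintf("  overlaps: %d (%s-%s bp)\n", s$n_overlaps,
              s$overlap_range[1], s$overlap_range[2]))
  cat(sprintf("  spacers:  %d (%s-%s bp)\n", s$n_spacers,
              s$spacer_range[1], s$spacer_range[2]))
  cat(sprintf("  control regions: %d (%s bp)\n", s$n_control_regions,
              paste(s$control_region_lengths, collapse = ", ")))
  cat(sprintf("  circle closes exactly: %s\n", x$closes_circle))
  invisible(x)
}

#' Composition table for the standard partitions
#'
#' Convenience builder for the classical composition-by-partition table:
#' whole genome, all PCGs (with codon positions), PCGs by strand (with codon
#' positions), tRNAs (pooled and by strand), and rRNAs. Gene partitions are
#' pooled over each feature's sense-strand sequence.
#'
#' @param annotation A `mito_annotation`.
#' @param residues Genome sequence.
#' @return data.frame of composition profiles, one per partition.
#' @export
composition_table <- function(annotation, residues) {
  f <- annotation$features
  pool <- function(genes) paste0(vapply(genes, function(g)
    feature_sequence(annotation, residues, g), ""), collapse = "")
  rows <- list(base_composition(residues, "Whole genome"))
  pcg <- f$gene[f$feature_class == "PCG"]
  if (length(pcg)) {
    rows <- c(rows, list(base_composition(pool(pcg), "Protein-coding genes")),
              list(codon_position_composition(annotation, residues, "all")))
    for (s in c("J", "N")) {
      gs <- f$gene[f$feature_class == "PCG" & f$strand == s]
      if (length(gs)) {
        rows <- c(rows,
          list(base_composition(pool(gs),
                                sprintf("Protein-coding genes %s-strand", s))),
          list(codon_position_composition(annotation, residues, s,
                 label_prefix = sprintf("PCG %s-strand", s))))
      }
    }
  }
  trna <- f$gene[f$feature_class == "tRNA"]
  if (length(trna)) {
    rows <- c(rows, list(base_composition(pool(trna), "tRNA genes")))
    for (s in c("J", "N")) {
      gs <- f$gene[f$feature_class == "tRNA" & f$strand == s]
      if (length(gs)) {
        rows <- c(rows, list(base_composition(pool(gs),
                    sprintf("tRNA genes %s-strand", s))))
      }
    }
  }
  rrna <- f$gene[f$feature_class == "rRNA"]
  if (length(rrna)) {
    rows <- c(rows, list(base_composition(pool(rrna), "rRNA genes")))
  }
  do.call(rbind, rows)
}
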