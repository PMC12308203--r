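# Packaged reference data: the curated annotation, composition and
# codon-usage tables of the Puto sinensis mitochondrial genome (the first
# mitogenome of the scale-insect family Putoidae), plus a schematic set of
# coccoid gene orders. These drive the worked examples and the regression
# tests of every descriptive stage.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "coccomito")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Packaged Puto sinensis reference tables
#'
#' `puto_feature_table()` returns the raw curated 37-row gene table
#' (including the published `printed_length` and `printed_intergenic`
#' columns, retained verbatim even where they disagree with the
#' coordinates; see the methods vignette). `puto_annotation()` parses it
#' into a [mito_annotation()] for the 18,830 bp circular genome.
#' `puto_codon_counts()` returns the published codon-usage counts as a
#' `codon_count_table` (with the published RSCU values as attribute
#' `printed_rscu`), and `puto_composition()` the published
#' composition-by-partition table.
#'
#' @return See above; `puto_genome_length()` returns 18830.
#' @export
puto_feature_table <- function() {
  read.table(extdata("puto_sinensis_features.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname puto_feature_table
#' @export
puto_genome_length <- function() 18830L

#' @rdname puto_feature_table
#' @export
puto_annotation <- function() {
  read_feature_table(extdata("puto_sinensis_features.tsv"),
                     genome_length = puto_genome_length())
}

#' @rdname puto_feature_table
#' @param code A [mito_genetic_code()].
#' @export
puto_codon_counts <- function(code = mito_genetic_code()) {
  tab <- read.table(extdata("puto_sinensis_codon_counts.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  out <- codon_count_table(stats::setNames(tab$count, tab$codon), code = code)
  attr(out, "printed_rscu") <- stats::setNames(tab$rscu,
                                               normalize_codons(tab$codon))
  out
}

#' @rdname puto_feature_table
#' @export
puto_composition <- function() {
  read.table(extdata("puto_sinensis_composition.tsv"), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
}

#' Schematic coccoid gene orders and group assignments
#'
#' A synthetic stand-in for the full published gene-order alignment of
#' scale-insect mitogenomes: the ancestral insect arrangement plus one
#' order per sampled taxon, in which only the rearrangements explicitly
#' documented for each taxon (the ND2-neighborhood clusters
#' trnM-ND2-trnW, trnI-ND2-trnY, trnY-ND2-trnW, trnI-ND2-trnW,
#' trnQ-ND2-trnW; the Matsucoccidae trnY relocation; the Monophlebidae
#' trnH-ND1-trnL1 and ND4-trnP-rrnS-trnT-cytb-trnS2 blocks) are encoded -
#' all other genes stay in the ancestral arrangement. The Puto sinensis
#' order is coordinate-derived from [puto_annotation()]. Distances between
#' these schematic orders are illustrative, not estimates for the real
#' genomes; cluster presence/absence is faithful.
#'
#' @return `coccoid_gene_orders()`: named list of `gene_order` objects
#'   (including `ancestor`); `coccoid_groups()`: named character vector
#'   taxon -> group (`neococcoid` / `non_neococcoid`); `nd2_patterns()`:
#'   named list of the five signed ND2-neighborhood cluster patterns.
#' @export
coccoid_gene_orders <- function() {
  read_gene_orders(extdata("coccoid_gene_orders_synthetic.txt"))
}

#' @rdname coccoid_gene_orders
#' @export
coccoid_groups <- function() {
  tab <- read.table(extdata("coccoid_groups.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stats::setNames(tab$group, tab$taxon)
}

#' @rdname coccoid_gene_orders
#' @export
nd2_patterns <- function() {
  list(
    "trnM-ND2-trnW" = c("trnM", "ND2", "trnW"),
    "trnI-ND2-trnY" = c("trnI", "ND2", "-trnY"),
    "trnY-ND2-trnW" = c("-trnY", "ND2", "trnW"),
    "trnI-ND2-trnW" = c("trnI", "ND2", "trnW"),
    "trnQ-ND2-trnW" = c("-trnQ", "ND2", "trnW")
  )
}
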