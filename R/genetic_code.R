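#' Genetic code with synonymous-family structure
#'
#' Wraps a Biostrings genetic code (by NCBI translation-table id) and derives
#' the structure the codon-usage and selection modules need: the codon to
#' amino-acid map, the stop-codon set, and the partition of sense codons into
#' synonymous families. The default, table 5 (invertebrate mitochondrial), is
#' the code used throughout insect mitogenomics: UGA encodes Trp, AGA/AGG
#' encode Ser (giving an 8-codon Ser family), and AUA encodes Met, leaving
#' only UAA/UAG as stops and 62 sense codons.
#'
#' @param id NCBI translation-table identifier as a character scalar
#'   (e.g. `"5"` invertebrate mitochondrial, `"1"` standard).
#' @return An object of class `genetic_code`: a list with `id`, `map` (named
#'   character vector, DNA codon -> single-letter amino acid, `"*"` = stop),
#'   `stops`, `sense` (sense codons), and `families` (named list of codon
#'   vectors, one per amino acid, plus a `"*"` family for the stops).
#' @examples
#' code <- mito_genetic_code()
#' code$map[["TGA"]]           # "W"
#' length(code$families$S)     # 8
#' @export
mito_genetic_code <- function(id = "5") {
  map <- Biostrings::getGeneticCode(as.character(id))
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  fam <- split(names(map), unname(map))
  structure(
    list(id = as.character(id), map = map, stops = stops, sense = sense,
         families = fam),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  sizes <- table(lengths(x$families[names(x$families) != "*"]))
  cat("Genetic code (NCBI table ", x$id, "): ", length(x$sense),
      " sense codons, stops ", paste(x$stops, collapse = "/"), "\n", sep = "")
  cat("Family sizes: ",
      paste(sprintf("%sx%s-fold", sizes, names(sizes)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Normalize codon spelling: RNA (U) accepted everywhere, stored as DNA (T).
normalize_codons <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# Display helper: DNA codons -> RNA spelling used in codon-usage tables.
codon_to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

# Round half away from zero, for report columns (so 1.875 -> 1.88).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
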