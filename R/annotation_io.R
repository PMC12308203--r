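#' @importFrom utils read.table write.table head tail
NULL

# Controlled gene-name vocabulary ---------------------------------------------

PCG_NAMES  <- c("COI", "COII", "COIII", "ATP6", "ATP8",
                "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6", "cytb")
RRNA_NAMES <- c("srRNA", "lrRNA")
TRNA_NAMES <- paste0("trn", c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                              "I", "K", "M", "F", "P", "T", "W", "Y", "V",
                              "S1", "S2", "L1", "L2"))
CR_NAMES   <- c("CR", "CR1", "CR2", "control_region")

feature_class_of <- function(name) {
  ifelse(name %in% PCG_NAMES, "PCG",
  ifelse(name %in% RRNA_NAMES, "rRNA",
  ifelse(grepl("^trn", name), "tRNA",
  ifelse(name %in% CR_NAMES, "control_region", "unknown"))))
}

#' Gene-name synonym table
#'
#' Annotation engines and GenBank records label mitochondrial genes
#' inconsistently (COX1 vs COI, nad4l vs ND4L, 16S vs lrRNA, ...). The
#' package ships an editable two-column table mapping observed labels to the
#' controlled vocabulary; `normalize_gene_name()` applies it
#' case-insensitively and passes already-canonical names through.
#'
#' @param path Optional path to a custom synonym TSV (columns `alias`,
#'   `canonical`); defaults to the table shipped with the package.
#' @return A data.frame with columns `alias` and `canonical`.
#' @export
gene_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "coccomito")
  }
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname gene_synonyms
#' @param name Character vector of raw gene labels.
#' @param synonyms Synonym table as returned by [gene_synonyms()].
#' @param warn Warn (rather than fail) on labels that cannot be mapped; the
#'   raw label is then retained.
#' @export
normalize_gene_name <- function(name, synonyms = gene_synonyms(), warn = TRUE) {
  canon <- c(PCG_NAMES, RRNA_NAMES, TRNA_NAMES, CR_NAMES)
  lut <- stats::setNames(synonyms$canonical, tolower(synonyms$alias))
  out <- vapply(name, function(nm) {
    if (nm %in% canon) return(nm)
    hit <- lut[tolower(nm)]
    if (!is.na(hit)) return(unname(hit))
    # case-insensitive match against the vocabulary itself
    ci <- canon[tolower(canon) == tolower(nm)]
    if (length(ci) == 1) return(ci)
    if (warn) warning("gene label not in vocabulary, kept as-is: ", nm,
                      call. = FALSE)
    nm
  }, character(1), USE.NAMES = FALSE)
  out
}

# Sequence records -------------------------------------------------------------

new_sequence_record <- function(id, residues, topology = "linear") {
  residues <- toupper(residues)
  residues <- gsub("U", "T", residues, fixed = TRUE)
  stopifnot(nchar(residues) > 0)
  structure(list(id = id, residues = residues, topology = topology),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record> ", x$id, ": ", nchar(x$residues), " bp (",
      x$topology, ")\n", sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin wrapper over Biostrings FASTA parsing that normalizes residues to
#' uppercase DNA (U mapped to T) and rejects non-IUPAC characters.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology flag stored on each record (`"circular"` or
#'   `"linear"`).
#' @return A list of `sequence_record` objects (fields `id`, `residues`,
#'   `topology`), one per FASTA record, in file order.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in: ", path)
  recs <- lapply(seq_along(set), function(i) {
    res <- toupper(as.character(set[[i]]))
    res <- gsub("U", "T", res, fixed = TRUE)
    bad <- regmatches(res, regexpr("[^ACGTRYSWKMBDHVN]", res))
    if (length(bad) > 0 && nzchar(bad)) {
      stop("non-IUPAC character '", bad, "' in record ", names(set)[i])
    }
    new_sequence_record(names(set)[i], res, topology)
  })
  recs
}

#' Write sequences to FASTA
#'
#' @param records A `sequence_record` or list of them.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# Annotations ------------------------------------------------------------------

empty_features <- function() {
  data.frame(gene = character(), strand = character(), start = integer(),
             end = integer(), wraps_origin = logical(),
             feature_class = character(), anticodon = character(),
             anticodon_start = integer(), anticodon_end = integer(),
             start_codon = character(), stop_codon = character(),
             stringsAsFactors = FALSE)
}

#' Construct a mitogenome annotation
#'
#' The central annotation container: a circular (or linear) genome length
#' plus an ordered, strand-aware gene feature table. Coordinates are 1-based
#' inclusive; a feature whose `end < start` must carry `wraps_origin = TRUE`
#' and is interpreted as running through the origin of the circle. Strands
#' use the insect-mitogenomics convention J (majority) / N (minority); `+`
#' and `-` are accepted as aliases.
#'
#' @param features data.frame with at least columns `gene`, `strand`,
#'   `start`, `end`; optional `wraps_origin`, `anticodon`,
#'   `anticodon_start`, `anticodon_end`, `start_codon`, `stop_codon`.
#' @param genome_length Genome length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `mito_annotation`: list with `genome_length`,
#'   `features` (sorted by `start`), and `topology`.
#' @export
mito_annotation <- function(features, genome_length,
                            topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length > 0)
  if (nrow(features) == 0) {
    features <- empty_features()
  } else {
    features$strand <- normalize_strand(features$strand)
    if (is.null(features$wraps_origin)) features$wraps_origin <- FALSE
    for (col in c("anticodon", "start_codon", "stop_codon")) {
      if (is.null(features[[col]])) features[[col]] <- NA_character_
    }
    for (col in c("anticodon_start", "anticodon_end")) {
      if (is.null(features[[col]])) features[[col]] <- NA_integer_
    }
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$feature_class <- feature_class_of(features$gene)
    if (anyDuplicated(features$gene)) {
      stop("duplicate gene names: ",
           paste(unique(features$gene[duplicated(features$gene)]),
                 collapse = ", "))
    }
    bad <- features$start < 1 | features$start > genome_length
    if (any(bad)) stop("feature start outside genome: ",
                       paste(features$gene[bad], collapse = ", "))
    inv <- features$end < features$start & !features$wraps_origin
    if (any(inv)) stop("end < start without wraps_origin flag: ",
                       paste(features$gene[inv], collapse = ", "))
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    keep <- c("gene", "strand", "start", "end", "wraps_origin",
              "feature_class", "anticodon", "anticodon_start",
              "anticodon_end", "start_codon", "stop_codon")
    features <- features[, keep]
  }
  structure(list(genome_length = genome_length, features = features,
                 topology = topology),
            class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  cls <- table(x$features$feature_class)
  cat("<mito_annotation> ", x$genome_length, " bp ", x$topology, ", ",
      nrow(x$features), " features (",
      paste(sprintf("%s %s", cls, names(cls)), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s == "+"] <- "J"
  s[s == "-"] <- "N"
  bad <- !(s %in% c("J", "N"))
  if (any(bad)) stop("unknown strand token: ",
                     paste(unique(strand[bad]), collapse = ", "))
  s
}

# "1820-2431" with hyphen or en dash -> c(1820, 2431)
parse_range <- function(x) {
  parts <- strsplit(gsub("–", "-", x), "-", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2) stop("cannot parse location range: ", x)
  as.integer(parts)
}

# "TAA 1592-1594" -> list(anticodon, start, end); "-" / "" -> NAs
parse_anticodon <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x %in% c("", "-")) {
    return(list(anticodon = NA_character_, start = NA_integer_,
                end = NA_integer_))
  }
  toks <- strsplit(x, "[ \t]+")[[1]]
  ac <- normalize_codons(toks[1])
  if (length(toks) >= 2) {
    r <- parse_range(toks[2])
    list(anticodon = ac, start = r[1], end = r[2])
  } else {
    list(anticodon = ac, start = NA_integer_, end = NA_integer_)
  }
}

#' Read a tabular gene feature list
#'
#' Parses a tab- or comma-separated feature table into a [mito_annotation()].
#' Accepted columns (header names case-insensitive): `gene`, `strand`, then
#' either a combined `location` column (`"1820-2431"`, hyphen or en dash) or
#' separate `start`/`end`, plus optional `anticodon` (triplet, optionally
#' followed by its location range), `start_codon`, `stop_codon`,
#' `wraps_origin`, and any extra columns (retained untouched in the returned
#' annotation's feature table is *not* done; extras are dropped).
#'
#' @param path Path to the table.
#' @param genome_length Genome length in bp (required: the table itself does
#'   not carry it).
#' @param sep Field separator; guessed from the first line when `NULL`.
#' @param normalize_names Map gene labels through [gene_synonyms()].
#' @return A `mito_annotation`.
#' @export
read_feature_table <- function(path, genome_length, sep = NULL,
                               normalize_names = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "\"", strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  if (!"gene" %in% names(tab) && "genes" %in% names(tab)) {
    names(tab)[names(tab) == "genes"] <- "gene"
  }
  need <- c("gene", "strand")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns gene and strand")
  }
  if ("location" %in% names(tab)) {
    rng <- t(vapply(tab$location, parse_range, integer(2)))
    tab$start <- rng[, 1]; tab$end <- rng[, 2]
  }
  if (!all(c("start", "end") %in% names(tab))) {
    stop("feature table needs start/end or a location column")
  }
  ac <- if ("anticodon" %in% names(tab)) {
    lapply(tab$anticodon, parse_anticodon)
  } else {
    rep(list(parse_anticodon(NA_character_)), nrow(tab))
  }
  gene <- if (normalize_names) normalize_gene_name(tab$gene) else tab$gene
  feats <- data.frame(
    gene = gene,
    strand = tab$strand,
    start = tab$start,
    end = tab$end,
    wraps_origin = if ("wraps_origin" %in% names(tab))
      as.logical(tab$wraps_origin) else FALSE,
    anticodon = vapply(ac, `[[`, "", "anticodon"),
    anticodon_start = vapply(ac, function(a) as.integer(a$start), integer(1)),
    anticodon_end = vapply(ac, function(a) as.integer(a$end), integer(1)),
    start_codon = if ("start_codon" %in% names(tab)) {
      ifelse(tab$start_codon %in% c("-", ""), NA_character_, tab$start_codon)
    } else NA_character_,
    stop_codon = if ("stop_codon" %in% names(tab)) {
      ifelse(tab$stop_codon %in% c("-", ""), NA_character_, tab$stop_codon)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  mito_annotation(feats, genome_length = genome_length)
}

# Feature sequence extraction --------------------------------------------------

#' Extract a feature's sequence on its sense strand
#'
#' Takes a feature row (or gene name) and the genome residues; N-strand
#' features are reverse-complemented so the result reads 5' to 3' on the
#' coding strand. Wrapping features are concatenated through the origin.
#'
#' @param annotation A `mito_annotation`.
#' @param residues Genome sequence as a single character string.
#' @param gene Gene label to extract.
#' @return Character scalar, the sense-strand sequence.
#' @export
feature_sequence <- function(annotation, residues, gene) {
  f <- annotation$features[annotation$features$gene == gene, , drop = FALSE]
  if (nrow(f) != 1) stop("gene not found in annotation: ", gene)
  seg <- if (f$wraps_origin) {
    paste0(substr(residues, f$start, annotation$genome_length),
           substr(residues, 1, f$end))
  } else {
    substr(residues, f$start, f$end)
  }
  if (f$strand == "N") seg <- revcomp(seg)
  seg
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Gene order extraction --------------------------------------------------------

#' Extract the signed circular gene order from an annotation
#'
#' Genes are listed in order of start coordinate; the orientation sign is
#' positive for J-strand and negative for N-strand features. Control regions
#' are excluded: the gene order is a permutation of genes, and control
#' regions are an emergent property of the gaps.
#'
#' @param annotation A `mito_annotation`.
#' @param taxon Optional taxon label attached to the order.
#' @return A `gene_order` object (see [gene_order()]).
#' @export
extract_gene_order <- function(annotation, taxon = NA_character_) {
  f <- annotation$features
  f <- f[f$feature_class != "control_region", , drop = FALSE]
  if (nrow(f) == 0) stop("annotation has no gene features")
  lab <- ifelse(f$strand == "N", paste0("-", f$gene), f$gene)
  gene_order(lab, taxon = taxon)
}

# GenBank flat files -----------------------------------------------------------

#' Read a GenBank flat file
#'
#' A deliberately small parser for GenBank flat files carrying `CDS`,
#' `tRNA`, `rRNA`, `D-loop` and `misc_feature` features with `/gene` or
#' `/product` qualifiers, such as the files this package itself writes and
#' typical single-genome submissions. Coordinates are kept 1-based
#' inclusive; `complement(a..b)` becomes strand N; a circular-origin
#' `join(a..L,1..b)` becomes a wrapping feature. Gene labels are normalized
#' through [gene_synonyms()]; unmappable labels are retained with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return List with elements `record` (a `sequence_record`) and
#'   `annotation` (a `mito_annotation`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file (no LOCUS): ", path)
  ltoks <- strsplit(trimws(locus[1]), "[ \t]+")[[1]]
  glen <- as.integer(ltoks[3])
  topology <- if (any(grepl("circular", locus[1]))) "circular" else "linear"
  id <- ltoks[2]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(fstart) == 0 || length(ostart) == 0) {
    stop("GenBank file missing FEATURES or ORIGIN section: ", path)
  }
  fl <- lines[(fstart + 1):(ostart - 1)]

  # sequence
  sl <- lines[(ostart + 1):length(lines)]
  sl <- sl[!grepl("^//", sl)]
  res <- toupper(gsub("[0-9 ]", "", paste(sl, collapse = "")))
  res <- gsub("U", "T", res, fixed = TRUE)
  if (nchar(res) != glen) {
    warning("LOCUS length ", glen, " != sequence length ", nchar(res))
  }

  # features: key lines start at col 6, qualifiers at col 22 with /
  keyline <- grepl("^ {5}\\S", fl)
  idx <- which(keyline)
  feats <- list()
  for (k in seq_along(idx)) {
    block <- fl[idx[k]:(if (k < length(idx)) idx[k + 1] - 1 else length(fl))]
    toks <- strsplit(trimws(block[1]), "[ \t]+")[[1]]
    key <- toks[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- paste0(toks[-1], collapse = "")
    # continuation lines of the location (no '/')
    qual1 <- grep("^ +/", block)
    extra <- if (length(qual1)) block[-1][seq_len(max(0, qual1[1] - 2))] else block[-1]
    extra <- extra[!grepl("/", extra)]
    loc <- paste0(loc, paste0(trimws(extra), collapse = ""))
    strand <- "J"
    if (grepl("^complement\\(", loc)) {
      strand <- "N"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    wraps <- FALSE
    if (grepl("^join\\(", loc)) {
      inner <- sub("^join\\((.*)\\)$", "\\1", loc)
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      rs <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
      start <- rs[[1]][1]; end <- rs[[length(rs)]][2]
      wraps <- end < start
    } else {
      r <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      start <- r[1]; end <- r[2]
    }
    if (max(start, if (wraps) 0 else end) > glen) {
      stop("feature beyond LOCUS length: ", block[1])
    }
    quals <- block[grepl("^ +/", block)]
    getq <- function(name) {
      m <- grep(paste0("^ +/", name, "="), quals, value = TRUE)
      if (length(m) == 0) return(NA_character_)
      gsub("\"", "", sub(paste0("^ +/", name, "="), "", m[1]))
    }
    gname <- getq("gene")
    if (is.na(gname)) gname <- getq("product")
    if (is.na(gname)) gname <- paste0(key, "_", start)
    ac <- getq("anticodon")  # written as "(pos:a..b,aa:X,seq:nnn)" or "NNN a..b"
    acs <- list(anticodon = NA_character_, start = NA_integer_,
                end = NA_integer_)
    if (!is.na(ac)) {
      if (grepl("pos:", ac)) {
        pos <- sub(".*pos:([0-9]+)\\.\\.([0-9]+).*", "\\1 \\2", ac)
        pr <- as.integer(strsplit(pos, " ")[[1]])
        sq <- if (grepl("seq:", ac)) sub(".*seq:([a-zA-Z]+).*", "\\1", ac)
              else NA_character_
        acs <- list(anticodon = if (is.na(sq)) NA_character_ else
                      normalize_codons(sq), start = pr[1], end = pr[2])
      } else {
        acs <- parse_anticodon(ac)
      }
    }
    feats[[length(feats) + 1]] <- data.frame(
      gene = gname, strand = strand, start = start, end = end,
      wraps_origin = wraps, anticodon = acs$anticodon,
      anticodon_start = acs$start, anticodon_end = acs$end,
      start_codon = NA_character_, stop_codon = NA_character_,
      stringsAsFactors = FALSE)
  }
  ftab <- do.call(rbind, feats)
  if (is.null(ftab)) ftab <- empty_features()
  ftab$gene <- normalize_gene_name(ftab$gene)
  ann <- mito_annotation(ftab, genome_length = glen, topology = topology)
  list(record = new_sequence_record(id, res, topology), annotation = ann)
}

#' Write a GenBank flat file
#'
#' Emits a minimal GenBank flat file (LOCUS, FEATURES, ORIGIN) for one
#' genome + annotation, sufficient to round-trip through [read_genbank()].
#'
#' @param record A `sequence_record`.
#' @param annotation A `mito_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, annotation, path) {
  L <- annotation$genome_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     %s   INV", record$id, L,
    annotation$topology), con)
  writeLines(sprintf("DEFINITION  %s mitochondrial genome.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- annotation$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$feature_class[i], PCG = "CDS", tRNA = "tRNA",
                  rRNA = "rRNA", control_region = "D-loop", "misc_feature")
    loc <- if (f$wraps_origin[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    } else {
      sprintf("%d..%d", f$start[i], f$end[i])
    }
    if (f$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene[i]), con)
    if (!is.na(f$anticodon[i]) && !is.na(f$anticodon_start[i])) {
      writeLines(sprintf(
        "                     /anticodon=\"%s %d-%d\"", f$anticodon[i],
        f$anticodon_start[i], f$anticodon_end[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  res <- tolower(record$residues)
  for (off in seq(1, nchar(res), by = 60)) {
    chunk <- substr(res, off, min(off + 59, nchar(res)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# Report -----------------------------------------------------------------------

#' Tabular annotation report
#'
#' Writes (or returns) the classical mitogenome structure table: gene,
#' strand, location, coordinate-derived length, anticodon and its location,
#' start/stop codons, and the signed intergenic column (negative = overlap
#' with the preceding gene, 0 = abutting, positive = spacer). By convention
#' the first feature's intergenic value is reported as 0: the gap closing
#' the circle back to the first feature is reported among the control
#' regions of the geometry summary instead of in this column.
#'
#' @param annotation A `mito_annotation`.
#' @param geometry A geometry report from [compute_geometry()]; computed on
#'   the fly when `NULL`.
#' @param path Optional output path; when given, a TSV is written.
#' @return A data.frame with the report columns (invisibly when writing).
#' @export
write_annotation_report <- function(annotation, geometry = NULL, path = NULL) {
  f <- annotation$features
  if (nrow(f) == 0) {
    rep <- data.frame(gene = character(), strand = character(),
                      location = character(), length = integer(),
                      anticodon = character(), start_codon = character(),
                      stop_codon = character(), intergenic = integer(),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(geometry)) geometry <- compute_geometry(annotation)
    lens <- geometry$gene_lengths[f$gene]
    sp <- geometry$spacers
    # spacer preceding each feature = junction whose downstream is the feature
    inter <- vapply(f$gene, function(g) {
      i <- which(sp$downstream == g)
      if (length(i) == 0) return(NA_integer_)
      as.integer(sp$length[i[1]])
    }, integer(1))
    inter[1] <- 0L  # wrap junction reported with the control regions
    ac <- ifelse(is.na(f$anticodon), "-",
                 paste0(f$anticodon,
                        ifelse(is.na(f$anticodon_start), "",
                               sprintf(" %d-%d", f$anticodon_start,
                                       f$anticodon_end))))
    rep <- data.frame(
      gene = f$gene, strand = f$strand,
      location = sprintf("%d-%d", f$start, f$end),
      length = as.integer(lens),
      anticodon = ac,
      start_codon = ifelse(is.na(f$start_codon), "-", f$start_codon),
      stop_codon = ifelse(is.na(f$stop_codon), "-", f$stop_codon),
      intergenic = inter,
      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
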