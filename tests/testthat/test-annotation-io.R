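test_that("read_fasta parses, normalizes case and maps U to T", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">one", "acgtacgtAA", ">two", "uuaaTTAA"), tmp)
  recs <- read_fasta(tmp)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "one")
  expect_equal(nchar(recs[[1]]$residues), 10)
  expect_equal(recs[[1]]$residues, "ACGTACGTAA")
  expect_equal(recs[[2]]$residues, "TTAATTAA")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT!ACGT"), bad)
  expect_error(read_fasta(bad))
})

test_that("feature tables parse locations, strands and anticodons", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("gene,strand,location,anticodon",
               "ATP6,J,1820–2431,-",       # en dash range
               "COI,+,1-1551,-",
               "trnL2,J,1560-1623,TAA 1592-1594"), tmp)
  ann <- read_feature_table(tmp, genome_length = 18830)
  f <- ann$features
  expect_equal(nrow(f), 3)
  a6 <- f[f$gene == "ATP6", ]
  expect_equal(gene_length(a6$start, a6$end, 18830), 612)
  expect_equal(f$strand[f$gene == "COI"], "J")  # "+" alias normalized
  l2 <- f[f$gene == "trnL2", ]
  expect_equal(l2$anticodon, "TAA")
  expect_equal(c(l2$anticodon_start, l2$anticodon_end), c(1592L, 1594L))
})

test_that("feature table validation rejects malformed annotations", {
  feats <- data.frame(gene = c("COI", "COI"), strand = c("J", "J"),
                      start = c(1, 100), end = c(50, 200))
  expect_error(mito_annotation(feats, 1000), "duplicate")
  feats2 <- data.frame(gene = "COI", strand = "J", start = 500, end = 100)
  expect_error(mito_annotation(feats2, 1000), "wraps_origin")
  feats3 <- data.frame(gene = "COI", strand = "?", start = 1, end = 100)
  expect_error(mito_annotation(feats3, 1000), "strand")
})

test_that("the packaged study annotation has the expected census", {
  ann <- puto_annotation()
  f <- ann$features
  expect_equal(ann$genome_length, 18830)
  expect_equal(nrow(f), 37)
  expect_equal(sum(f$feature_class == "tRNA"), 22)
  expect_equal(sum(f$feature_class == "PCG"), 13)
  expect_equal(sum(f$feature_class == "rRNA"), 2)
  expect_true(all(diff(f$start) > 0))
  expect_true(all(f$start >= 1 & f$end <= ann$genome_length))
  # duplicate tRNA isotypes are keyed by anticodon
  expect_equal(f$anticodon[f$gene == "trnS1"], "TGA")
  expect_equal(f$anticodon[f$gene == "trnS2"], "TCT")
  expect_equal(f$anticodon[f$gene == "trnL1"], "TAG")
  expect_equal(f$anticodon[f$gene == "trnL2"], "TAA")
})

test_that("gene name normalization maps engine labels to the vocabulary", {
  expect_equal(normalize_gene_name(c("cox1", "NAD1", "16S", "trnL2")),
               c("COI", "ND1", "lrRNA", "trnL2"))
  expect_warning(out <- normalize_gene_name("mystery_orf"), "vocabulary")
  expect_equal(out, "mystery_orf")
})

test_that("extract_gene_order is start-ordered, signed, control-region free", {
  ann <- puto_annotation()
  ord <- extract_gene_order(ann, taxon = "Puto_sinensis")
  expect_length(ord, 37)
  expect_equal(ord$genes[1:5], c("COI", "trnL2", "trnD", "ATP8", "ATP6"))
  expect_equal(ord$signs[1:5], rep(1L, 5))
  expect_equal(ord$signs[ord$genes == "srRNA"], -1L)

  single <- mito_annotation(
    data.frame(gene = "COI", strand = "J", start = 1, end = 300), 1000)
  expect_length(extract_gene_order(single), 1)

  # wrapping feature placed by its start coordinate
  wrap <- mito_annotation(
    data.frame(gene = c("COI", "ND2", "cytb"), strand = "J",
               start = c(101, 401, 900), end = c(400, 800, 50),
               wraps_origin = c(FALSE, FALSE, TRUE)), 1000)
  expect_equal(extract_gene_order(wrap)$genes, c("COI", "ND2", "cytb"))
})

test_that("GenBank reading converts coordinates, strands and labels", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       test 6000 bp    DNA     circular   INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..6000",
    "     CDS             complement(4218..5120)",
    "                     /gene=\"nad1\"",
    "     CDS             1..1551",
    "                     /gene=\"cox1\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("aaaaaaaaaa", 6), collapse = " ")),
    "//"), gb)
  out <- suppressWarnings(read_genbank(gb))
  f <- out$annotation$features
  nd1 <- f[f$gene == "ND1", ]
  expect_equal(nd1$strand, "N")
  expect_equal(gene_length(nd1$start, nd1$end, 6000), 903)
  expect_equal(f$strand[f$gene == "COI"], "J")
})

test_that("synthetic GenBank round-trips to the generating annotation", {
  sim <- simulate_mitogenome(sim_config(seed = 11))
  gb <- tempfile(fileext = ".gb")
  write_genbank(sim$record, sim$annotation, gb)
  rt <- read_genbank(gb)
  expect_equal(rt$record$residues, sim$record$residues)
  cols <- c("gene", "strand", "start", "end", "anticodon",
            "anticodon_start", "anticodon_end")
  expect_equal(rt$annotation$features[, cols],
               sim$annotation$features[, cols])
})

test_that("annotation report round-trips through read_feature_table", {
  ann <- puto_annotation()
  rep <- write_annotation_report(ann)
  tmp <- tempfile(fileext = ".tsv")
  write.table(rep, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_feature_table(tmp, genome_length = puto_genome_length())
  cols <- c("gene", "strand", "start", "end", "anticodon",
            "anticodon_start", "anticodon_end", "start_codon", "stop_codon")
  expect_equal(back$features[, cols], ann$features[, cols])

  empty <- mito_annotation(
    data.frame(gene = character(), strand = character(),
               start = integer(), end = integer()), 1000)
  expect_equal(nrow(write_annotation_report(empty)), 0)
})
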