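test_that("skews follow the defining formulas and conventions", {
  expect_equal(at_skew(50, 50), 0)
  expect_equal(at_skew(100, 0), 1)
  expect_equal(round_skew(at_skew(41.2, 47.8)), -0.074)
  expect_equal(round_skew(at_skew(47.9, 44.6)), 0.036)
  expect_true(is.na(at_skew(0, 0)))   # undefined, not zero
  expect_true(is.na(gc_skew(0, 0)))
  # antisymmetry over random inputs
  set.seed(42)
  a <- runif(50, 0, 60); t <- runif(50, 0, 60)
  expect_equal(at_skew(a, t), -at_skew(t, a))
})

test_that("base composition excludes ambiguity codes from the denominator", {
  p <- base_composition("AATT")
  expect_equal(p$pct_a, 50); expect_equal(p$pct_t, 50)
  expect_equal(p$at_skew, 0)
  expect_equal(base_composition("AAAA")$at_skew, 1)
  pn <- base_composition("AATTNN")
  expect_equal(pn$pct_at, 100)  # N not counted
  expect_equal(pn$pct_a + pn$pct_t + pn$pct_g + pn$pct_c, 100)
})

test_that("codon-position composition works on the sense strand", {
  ann <- mito_annotation(
    data.frame(gene = "ND2", strand = "J", start = 1, end = 6), 20)
  res <- "ATGATTAAAAAAAAAAAAAA"
  prof <- codon_position_composition(ann, res)
  expect_equal(prof$pct_a[1], 100)            # position 1: A,A
  expect_equal(prof$pct_t[2], 100)            # position 2: T,T
  expect_equal(prof$pct_g[3] + prof$pct_t[3], 100)  # position 3: G,T

  # same gene on the N strand: identical profiles after reverse complement
  annN <- mito_annotation(
    data.frame(gene = "ND2", strand = "N", start = 1, end = 6), 20)
  resN <- paste0(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGATT"))),
    "AAAAAAAAAAAAAA")
  profN <- codon_position_composition(annN, resN)
  expect_equal(profN[, -1], prof[, -1])

  badann <- mito_annotation(
    data.frame(gene = "ND2", strand = "J", start = 1, end = 5), 20)
  expect_error(codon_position_composition(badann, res), "ND2")
})

test_that("gene lengths handle ordinary and origin-wrapping features", {
  expect_equal(gene_length(5195, 6388, 18830), 1194)
  expect_equal(gene_length(12282, 12321, 18830), 40)
  expect_equal(gene_length(18829, 2, 18830, wraps_origin = TRUE), 4)
})

test_that("geometry computes signed spacers on the circular order", {
  ann <- mito_annotation(
    data.frame(gene = c("COI", "ND2", "cytb"), strand = "J",
               start = c(1, 11, 31), end = c(10, 20, 90)), 100)
  g <- compute_geometry(ann, control_region_min = 1000)
  sp <- g$spacers
  expect_equal(sp$length[sp$upstream == "COI"], 0)      # abutting
  expect_equal(sp$length[sp$upstream == "ND2"], 10)     # spacer
  expect_equal(sp$length[sp$upstream == "cytb"], 10)    # wrap junction
  expect_true(g$closes_circle)
  expect_equal(g$summary$n_overlaps + g$summary$n_spacers +
                 g$summary$n_control_regions + g$summary$n_abutting,
               nrow(ann$features))
})

test_that("study-genome geometry reproduces the published structure", {
  ann <- puto_annotation()
  g <- compute_geometry(ann)
  sp <- g$spacers
  expect_equal(sp$length[sp$downstream == "ATP6"], -7)
  expect_equal(sp$length[sp$downstream == "srRNA"], 2350)
  expect_equal(sp$class[sp$downstream == "srRNA"], "control_region")
  # wrap-around gap back to COI is the second control region
  expect_equal(sp$length[sp$downstream == "COI"], 2453)
  expect_equal(g$summary$n_control_regions, 2)
  expect_true(g$closes_circle)
})

test_that("the intergenic report column matches the published values", {
  ann <- puto_annotation()
  raw <- puto_feature_table()
  rep <- write_annotation_report(ann)
  expect_equal(rep$gene, raw$gene)
  # three published intergenic values are inconsistent with the published
  # coordinates (trnA: coords give -16, printed -15; trnR: coords give -8,
  # printed -4; ND5: coords give 21, printed 17); all other rows agree
  disagree <- rep$gene[rep$intergenic != raw$printed_intergenic]
  expect_equal(disagree, c("trnA", "trnR", "ND5"))
  expect_equal(rep$intergenic[rep$gene == "ND5"], 21)
})

test_that("composition table covers the standard partitions", {
  sim <- simulate_mitogenome(sim_config(seed = 5))
  tab <- composition_table(sim$annotation, sim$record$residues)
  expect_true(all(c("Whole genome", "Protein-coding genes", "tRNA genes",
                    "rRNA genes") %in% tab$partition))
  expect_true(all(abs(tab$pct_a + tab$pct_t + tab$pct_g + tab$pct_c - 100)
                  < 1e-9))
  expect_true(all(tab$at_skew >= -1 & tab$at_skew <= 1, na.rm = TRUE))
})
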