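test_that("canonicalization anchors, rotates and reflects", {
  o <- gene_order(c("COI", "trnL2", "-ND1", "cytb"))
  expect_equal(canonicalize(o)$genes, o$genes)  # already anchored
  rot <- gene_order(c("-ND1", "cytb", "COI", "trnL2"))
  expect_equal(canonicalize(rot)$genes, canonicalize(o)$genes)
  expect_equal(canonicalize(rot)$signs, canonicalize(o)$signs)
  # anchor on the minority strand: global flip makes it positive
  flip <- gene_order(c("-COI", "ND1", "-cytb", "trnL2"))
  can <- canonicalize(flip)
  expect_equal(can$genes[1], "COI")
  expect_equal(can$signs[1], 1L)
  expect_equal(breakpoint_distance(can, flip), 0)
})

test_that("breakpoint distance counts adjacency differences", {
  a <- gene_order(c("COI", "ND1", "ND2", "cytb", "trnM"))
  expect_equal(breakpoint_distance(a, a), 0)
  # one gene moved elsewhere: 3 adjacencies differ
  b <- gene_order(c("COI", "ND2", "cytb", "ND1", "trnM"))
  expect_equal(breakpoint_distance(a, b), 3)
  # identity under rotation and reflection
  rot <- gene_order(c("ND2", "cytb", "trnM", "COI", "ND1"))
  expect_equal(breakpoint_distance(a, rot), 0)
  refl <- gene_order(rev(c("-COI", "-ND1", "-ND2", "-cytb", "-trnM")))
  expect_equal(breakpoint_distance(a, refl), 0)
})

test_that("breakpoint distance is a pseudometric on random signed orders", {
  set.seed(77)
  for (r in 1:200) {
    a <- random_order(12); b <- random_order(12)
    dab <- breakpoint_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, breakpoint_distance(b, a))
    expect_equal(breakpoint_distance(a, a), 0)
  }
  for (r in 1:50) {
    a <- random_order(10); b <- random_order(10); c <- random_order(10)
    expect_lte(breakpoint_distance(a, c),
               breakpoint_distance(a, b) + breakpoint_distance(b, c))
  }
})

test_that("cluster search is circular, signed and orientation-aware", {
  puto <- extract_gene_order(puto_annotation(), taxon = "Puto_sinensis")
  hit <- find_cluster(puto, c("trnM", "ND2", "trnW"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$orientation, "forward")
  expect_equal(nrow(find_cluster(puto, c("trnI", "ND2", "-trnY"))), 0)

  # match across the circular origin
  o <- gene_order(c("ND2", "trnW", "COI", "cytb", "trnI", "trnM"))
  expect_equal(find_cluster(o, c("trnM", "ND2", "trnW"))$position, 6)
  # inverted occurrence
  oi <- gene_order(c("COI", "-trnW", "-ND2", "-trnM", "cytb"))
  hi <- find_cluster(oi, c("trnM", "ND2", "trnW"))
  expect_equal(hi$orientation, "inverted")
  expect_equal(nrow(find_cluster(oi, c("trnM", "ND2", "trnW"),
                                 orientation_sensitive = FALSE)), 0)
})

test_that("cluster search is invariant under rotation and global flip", {
  set.seed(5)
  base <- extract_gene_order(puto_annotation())
  pat <- c("trnM", "ND2", "trnW")
  for (r in 1:5) {
    k <- sample(37, 1)
    idx <- c(k:37, seq_len(k - 1))
    rot <- gene_order(paste0(ifelse(base$signs[idx] < 0, "-", ""),
                             base$genes[idx]))
    expect_equal(nrow(find_cluster(rot, pat)), 1)
  }
  flip <- gene_order(rev(paste0(ifelse(base$signs < 0, "", "-"),
                                base$genes)))
  expect_equal(nrow(find_cluster(flip, pat)), 1)
  expect_equal(find_cluster(flip, pat)$orientation, "inverted")
})

test_that("apomorphy scan flags group-restricted derived clusters", {
  orders <- coccoid_gene_orders()
  groups <- coccoid_groups()
  scan <- apomorphy_scan(orders, nd2_patterns(), groups)
  d <- scan$diagnostic
  # the ancestral cluster is fixed in the non-neococcoids and absent from
  # every neococcoid
  anc <- d[d$pattern == "trnM-ND2-trnW", ]
  expect_equal(anc$group, "non_neococcoid")
  expect_true(anc$fixed)
  expect_equal(scan$fractions["non_neococcoid", "trnM-ND2-trnW"], 1)
  expect_equal(scan$fractions["neococcoid", "trnM-ND2-trnW"], 0)
  # the derived ND2 clusters are restricted to the neococcoids
  for (p in c("trnI-ND2-trnY", "trnY-ND2-trnW", "trnQ-ND2-trnW")) {
    expect_true(p %in% d$pattern)
    expect_equal(d$group[d$pattern == p], "neococcoid")
    expect_equal(scan$fractions["non_neococcoid", p], 0)
  }
  expect_error(apomorphy_scan(orders, list(x = c("nope", "ND2")), groups),
               "unknown gene label")
})

test_that("constructed groups behave as expected in the scan", {
  orders <- list(a1 = gene_order(c("COI", "A", "B", "C")),
                 a2 = gene_order(c("COI", "A", "B", "C")),
                 b1 = gene_order(c("COI", "B", "A", "C")),
                 b2 = gene_order(c("COI", "B", "C", "A")))
  groups <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  scan <- apomorphy_scan(orders, list(AB = c("A", "B"), BC = c("B", "C")),
                         groups)
  expect_true("AB" %in% scan$diagnostic$pattern)     # fixed in g1 only
  expect_false("BC" %in% scan$diagnostic$pattern)    # present in both groups
})

test_that("distance matrix and NJ tree recover simple topologies", {
  orders <- list(
    A = gene_order(c("COI", "a", "b", "c", "d", "e")),
    B = gene_order(c("COI", "a", "b", "c", "d", "e")),
    C = gene_order(c("COI", "c", "a", "b", "e", "d")))
  d <- order_distance_matrix(orders)
  expect_true(isSymmetric(d))
  expect_equal(d["A", "B"], 0)
  expect_gt(d["A", "C"], 0)
  tree <- ape::read.tree(text = nj_tree(d))
  expect_setequal(tree$tip.label, c("A", "B", "C"))

  # additive 4-taxon matrix: NJ recovers the generating topology
  dm <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 2,
                 8, 8, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- ape::read.tree(text = nj_tree(dm))
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
                ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
  # all-equal distances: valid tree, no crash
  de <- matrix(4, 4, 4, dimnames = dimnames(dm)); diag(de) <- 0
  expect_no_error(nj_tree(de))
})

test_that("gene-order files round-trip", {
  orders <- coccoid_gene_orders()
  tmp <- tempfile(fileext = ".txt")
  write_gene_orders(orders, tmp)
  back <- read_gene_orders(tmp)
  expect_equal(names(back), names(orders))
  expect_equal(back$Puto_sinensis$genes, orders$Puto_sinensis$genes)
  expect_equal(back$Puto_sinensis$signs, orders$Puto_sinensis$signs)
})
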