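test_that("codon counting is exact and warns on internal stops", {
  code <- code5
  tab <- count_codons("TTATTATTG", code)
  expect_equal(unname(tab[["TTA"]]), 2)
  expect_equal(unname(tab[["TTG"]]), 1)
  expect_equal(sum(tab), 3)
  # conservation over a multi-CDS set
  sim <- simulate_mitogenome(sim_config(seed = 2))
  cds <- unlist(sim$truth$cds)
  tab2 <- count_codons(cds, code)
  expect_equal(sum(tab2), sum(nchar(cds)) / 3)
  expect_warning(count_codons("ATTTAAATT", code), "internal stop")
  expect_error(count_codons("ATTA", code), "divisible")
})

test_that("RSCU reproduces hand-computed family values", {
  code <- code5
  leu <- codon_count_table(
    c(UUA = 406, UUG = 24, CUU = 25, CUC = 4, CUA = 34, CUG = 1), code)
  r <- rscu(leu)
  expect_equal(r$rscu_rounded[r$codon == "UUA"], 4.93)
  ser <- codon_count_table(
    c(UCU = 48, UCC = 7, UCA = 85, UCG = 2, AGU = 19, AGC = 1, AGA = 43,
      AGG = 7), code)
  expect_equal(rscu(ser)$rscu_rounded[rscu(ser)$codon == "UCA"], 3.21)
  # uniform usage in any family gives RSCU 1
  unif <- codon_count_table(stats::setNames(rep(5, 4),
                                            code$families[["V"]]), code)
  expect_true(all(rscu(unif)$rscu[rscu(unif)$amino_acid == "V"] == 1))
})

test_that("RSCU family sums equal family size and scale invariance holds", {
  code <- code5
  tab <- random_codon_table(7, code)
  r <- rscu(tab)
  sums <- tapply(r$rscu, r$amino_acid, sum)
  sizes <- tapply(r$family_size, r$amino_acid, unique)
  expect_equal(as.numeric(sums[names(sizes)]), as.numeric(sizes))
  tab10 <- codon_count_table(unclass(tab) * 10, code)
  expect_equal(rscu(tab10)$rscu, r$rscu)
})

test_that("ENC hits its limit cases and matches the brute-force oracle", {
  code <- code5
  # uniform usage of all sense codons at large n -> maximum (62 for code 5)
  unif <- codon_count_table(stats::setNames(rep(1000, 62), code$sense), code)
  expect_equal(enc(unif), 62)
  # exactly one codon used per amino acid -> 20
  one_each <- codon_count_table(
    stats::setNames(rep(200, 20),
                    vapply(code$families[names(code$families) != "*"],
                           `[`, "", 1)), code)
  expect_equal(enc(one_each), 20)
  # random tables agree with an independent straightforward implementation
  for (s in 1:5) {
    tab <- random_codon_table(s, code)
    expect_equal(enc(tab), oracle_enc(unclass(tab), code), tolerance = 1e-9)
  }
})

test_that("ENC decreases as usage concentrates within a family", {
  code <- code5
  tab <- random_codon_table(3, code)
  fam <- code$families[["L"]]
  rare <- fam[which.min(tab[fam])]
  top <- fam[which.max(tab[fam])]
  shifted <- unclass(tab)
  shifted[rare] <- shifted[rare] - 1
  shifted[top] <- shifted[top] + 1
  expect_lte(enc(codon_count_table(shifted, code)), enc(tab))
})

test_that("CBI hits its limit cases and matches the brute-force oracle", {
  code <- code5
  fams <- code$families[names(code$families) != "*"]
  only_opt <- codon_count_table(
    stats::setNames(rep(50, 20), vapply(fams, `[`, "", 1)), code)
  expect_equal(cbi(only_opt), 1)
  unif <- codon_count_table(
    stats::setNames(rep(30, 62), code$sense), code)
  expect_equal(cbi(unif), 0)
  for (s in 6:10) {
    tab <- random_codon_table(s, code)
    expect_equal(cbi(tab), oracle_cbi(unclass(tab), code), tolerance = 1e-9)
  }
})

test_that("GC and GC3 are computed over sense codons", {
  code <- code5
  ggg <- codon_count_table(c(GGG = 10), code)
  expect_equal(unname(gc_content(ggg)), c(1, 1))
  gga <- codon_count_table(c(GGA = 10), code)
  expect_equal(unname(gc_content(gga)), c(2 / 3, 0))
  # AT enrichment at third positions: GC3 below the positions-1+2 average
  tab <- puto_codon_counts()
  g <- gc_content(tab)
  gc12 <- (3 * g[["gc"]] - g[["gc3"]]) / 2
  expect_lt(g[["gc3"]], gc12)
})

test_that("bias correlations report signs and tolerate degenerate input", {
  m <- data.frame(gc3 = c(0.1, 0.2, 0.3, 0.4))
  m$gc <- m$gc3 + 0.05
  m$enc <- 30 + 40 * m$gc3          # ENC strictly increasing in GC3
  m$cbi <- 0.9 - m$gc3
  bc <- bias_correlations(m)
  expect_equal(bc$sign[bc$pair == "ENC~GC3"], "+")
  expect_equal(bc$sign[bc$pair == "CBI~GC3"], "-")
  m2 <- m; m2$cbi <- 0.5            # constant metric: undefined, no crash
  bc2 <- bias_correlations(m2)
  expect_true(all(is.na(bc2$rho[grepl("CBI", bc2$pair)])))
})

test_that("a simulated AT gradient reproduces the empirical sign pattern", {
  panel <- simulate_codon_panel(seq(0.75, 0.92, length.out = 8),
                                n_codons = 8000, seed = 9)
  bc <- bias_correlations(panel[, c("enc", "cbi", "gc", "gc3")])
  expect_equal(bc$sign,
               c("+", "+", "-", "-", "-"))  # ENC~GC, ENC~GC3, CBI~GC, CBI~GC3, ENC~CBI
})
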