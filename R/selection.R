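# Nei-Gojobori (1986) counting of synonymous/nonsynonymous sites and
# differences, with Jukes-Cantor distance correction. This is the package's
# selection engine; the maximum-likelihood codon models used elsewhere in
# the field are deliberately out of scope (see the methods vignette).

codon_neighbors <- function(codon, pos) {
  b <- strsplit(codon, "")[[1]]
  other <- setdiff(c("A", "C", "G", "T"), b[pos])
  vapply(other, function(nt) {
    bb <- b; bb[pos] <- nt; paste0(bb, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' NG86 fractional site counting: at each of the three positions the
#' synonymous fraction is the proportion of single-nucleotide neighbors
#' encoding the same amino acid; neighbors that are stop codons are
#' excluded from the denominator at that position. Synonymous +
#' nonsynonymous sites always sum to 3.
#'
#' @param codon A sense codon (DNA or RNA spelling).
#' @param code A [mito_genetic_code()].
#' @return Named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
ng86_sites <- function(codon, code = mito_genetic_code()) {
  codon <- normalize_codons(codon)
  if (codon %in% code$stops) stop("stop codon has no NG86 sites: ", codon)
  aa <- code$map[[codon]]
  syn <- 0
  for (pos in 1:3) {
    nb <- codon_neighbors(codon, pos)
    nb <- nb[!(nb %in% code$stops)]
    if (length(nb) == 0) next
    syn <- syn + sum(code$map[nb] == aa) / length(nb)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Average synonymous/nonsynonymous difference counts between two codons,
# over all minimal substitution pathways; pathways passing through a stop
# codon are excluded (all-stop pathway sets fall back to including them).
ng86_codon_diffs <- function(c1, c2, code) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else
    if (length(pos) == 2) list(pos, rev(pos)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) pos[o])
  score_path <- function(order) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    syn <- 0; nonsyn <- 0
    for (p in order) {
      prev <- paste0(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste0(cur, collapse = "")
      if (nxt %in% code$stops || prev %in% code$stops) return(NULL)
      if (code$map[[prev]] == code$map[[nxt]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  scores <- Filter(Negate(is.null), lapply(perms, score_path))
  if (length(scores) == 0) {
    # no stop-free pathway: score through stops rather than fail
    scores <- lapply(perms, function(order) {
      cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
      syn <- 0; nonsyn <- 0
      for (p in order) {
        prev <- paste0(cur, collapse = ""); cur[p] <- tgt[p]
        nxt <- paste0(cur, collapse = "")
        if (identical(code$map[[prev]], code$map[[nxt]])) syn <- syn + 1
        else nonsyn <- nonsyn + 1
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  Reduce(`+`, scores) / length(scores)
}

#' Pairwise Ka/Ks by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (equal-weight averaging over minimal
#' substitution pathways for multi-difference codons, stop-traversing
#' pathways excluded), then applies the Jukes-Cantor correction
#' d = -3/4 log(1 - 4p/3) to both proportions. Saturated proportions
#' (p >= 3/4) yield `NA` with a `saturated` flag rather than a number.
#'
#' @param seq1,seq2 Gap-free, codon-aligned sense-strand CDS sequences of
#'   equal length divisible by 3.
#' @param code A [mito_genetic_code()].
#' @param gene Optional gene label carried into the result.
#' @return A `selection_estimate`: one-row data.frame with columns `gene`,
#'   `N`, `S` (site counts), `Nd`, `Sd` (difference counts), `pn`, `ps`,
#'   `ka`, `ks`, `ka_ks`, `saturated`.
#' @export
ng86_kaks <- function(seq1, seq2, code = mito_genetic_code(),
                      gene = NA_character_) {
  s1 <- normalize_codons(seq1); s2 <- normalize_codons(seq2)
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal length")
  if (nchar(s1) %% 3 != 0) stop("length not divisible by 3")
  n_cod <- nchar(s1) / 3
  cod1 <- substring(s1, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  cod2 <- substring(s2, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  # terminal stop codons are not informative for selection: drop a shared
  # final stop pair, reject internal stops
  if (cod1[n_cod] %in% code$stops && cod2[n_cod] %in% code$stops) {
    cod1 <- cod1[-n_cod]; cod2 <- cod2[-n_cod]; n_cod <- n_cod - 1
  }
  if (any(cod1 %in% code$stops) || any(cod2 %in% code$stops)) {
    stop("internal stop codon in alignment", if (!is.na(gene))
      paste0(" (", gene, ")") else "")
  }
  sites1 <- vapply(cod1, ng86_sites, numeric(2), code = code)
  sites2 <- vapply(cod2, ng86_sites, numeric(2), code = code)
  S <- (sum(sites1["syn", ]) + sum(sites2["syn", ])) / 2
  N <- (sum(sites1["nonsyn", ]) + sum(sites2["nonsyn", ])) / 2
  diffs <- mapply(function(a, b) ng86_codon_diffs(a, b, code), cod1, cod2)
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)  # saturation
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps); ka <- jc(pn)
  saturated <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  out <- data.frame(gene = gene, N = N, S = S, Nd = Nd, Sd = Sd,
                    pn = pn, ps = ps, ka = ka, ks = ks, ka_ks = ratio,
                    saturated = saturated, stringsAsFactors = FALSE)
  class(out) <- c("selection_estimate", class(out))
  out
}

#' Per-gene, per-taxon Ka/Ks panel against a reference taxon
#'
#' Runs [ng86_kaks()] for every shared protein-coding gene between each
#' taxon and the reference. Sequences must be pre-aligned codon-wise; as a
#' convenience for simulated data, `trim = TRUE` trims each pair to the
#' shorter length rounded down to a codon multiple, and warns - do not use
#' this on real alignments.
#'
#' @param cds_by_taxon Named list (taxon -> named character vector of
#'   sense-strand CDS by gene label).
#' @param reference Name of the reference taxon in `cds_by_taxon`.
#' @param code A [mito_genetic_code()].
#' @param trim Apply the naive equal-length trim rule (simulator data only).
#' @return List with `table` (long-format data.frame of estimates) and
#'   `summary` (`n_defined`, `n_below_one`).
#' @export
kaks_panel <- function(cds_by_taxon, reference,
                       code = mito_genetic_code(), trim = FALSE) {
  stopifnot(reference %in% names(cds_by_taxon))
  ref <- cds_by_taxon[[reference]]
  taxa <- setdiff(names(cds_by_taxon), reference)
  rows <- list()
  for (tx in taxa) {
    genes <- intersect(names(ref), names(cds_by_taxon[[tx]]))
    for (g in genes) {
      a <- ref[[g]]; b <- cds_by_taxon[[tx]][[g]]
      if (nchar(a) != nchar(b)) {
        if (!trim) stop("unequal CDS lengths for ", g, " (", tx,
                        "); supply codon alignments or set trim = TRUE")
        warning("trimming ", g, " (", tx, ") to a common codon length; ",
                "only appropriate for simulated data", call. = FALSE)
        L <- 3 * (min(nchar(a), nchar(b)) %/% 3)
        a <- substr(a, 1, L); b <- substr(b, 1, L)
      }
      est <- ng86_kaks(a, b, code = code, gene = g)
      est$taxon <- tx
      rows[[length(rows) + 1]] <- est
    }
  }
  tab <- do.call(rbind, rows)
  defined <- tab$ka_ks[!is.na(tab$ka_ks)]
  list(table = tab,
       summary = list(n_pairs = nrow(tab), n_defined = length(defined),
                      n_below_one = sum(defined < 1)))
}
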