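# Synthetic mitogenome generator. Produces genomes with the statistical
# structure the descriptive pipeline assumes - AT-rich composition, genes on
# two strands with overlaps/spacers/control regions, codon usage drawn from
# an empirical frequency table, tRNAs built from structural templates of
# known cloverleaf class - together with a ground-truth record of every
# quantity the pipeline later measures. Defaults mirror the study genome:
# 18,830 bp, 90.7% A+T, 37 genes, tRNA class counts 8 full / 8 T-armless /
# 5 D-armless / 1 minimal.

# Named pseudo-random streams: one derived seed per sub-generator, so adding
# a generator never shifts another's draws.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# tRNA structural templates ----------------------------------------------------

# Fixed helix/loop segments. Poly-A stretches replace absent arms: adenine
# runs cannot base-pair with themselves, so an absent arm cannot be
# rediscovered by the hairpin search.
TRNA_SEG <- list(
  acc5 = "GGTATTA", acc3 = "TAATACC", disc = "A",
  link1 = "TA", link2 = "A",
  d_arm = "ACCTAAATAAAAGGT",     # 4-pair stem, 7-nt loop
  d_absent = "AAAAAAA",
  ac5 = "CTTGA", ac3 = "TCAAG",  # 5-pair anticodon stem
  var = "AAAA",
  t_arm = "GCTAATTAAAAATTAGC",   # 5-pair stem, 7-nt loop
  t_absent = "AAAAAAAA"
)

#' Build a tRNA gene sequence of a requested cloverleaf class
#'
#' Assembles a tRNA template (sense strand, DNA) from fixed structural
#' segments: acceptor stem, optional D arm, anticodon arm with the supplied
#' anticodon centered in its 7-nt loop, optional T arm, and a discriminator
#' base. Absent arms are replaced by short adenine runs, which cannot
#' base-pair internally.
#'
#' @param class `"full"`, `"D-armless"`, `"T-armless"` or `"minimal"`.
#' @param anticodon Anticodon triplet (DNA spelling, as annotated).
#' @return List with `sequence`, `anticodon_offset` (1-based position of the
#'   anticodon within the sequence), and `class`.
#' @export
trna_template <- function(class = c("full", "D-armless", "T-armless",
                                    "minimal"),
                          anticodon = "CAT") {
  class <- match.arg(class)
  anticodon <- normalize_codons(anticodon)
  stopifnot(nchar(anticodon) == 3)
  s <- TRNA_SEG
  ac_arm <- paste0(s$ac5, "TT", anticodon, "AA", s$ac3)
  parts <- if (class == "minimal") {
    list(s$acc5, "AAA", ac_arm, "AAAA", s$acc3, s$disc)
  } else {
    list(s$acc5, s$link1,
         if (class == "D-armless") s$d_absent else s$d_arm,
         s$link2, ac_arm, s$var,
         if (class == "T-armless") s$t_absent else s$t_arm,
         s$acc3, s$disc)
  }
  seq <- paste0(unlist(parts), collapse = "")
  before_ac <- if (class == "minimal") {
    nchar(s$acc5) + 3
  } else {
    nchar(s$acc5) + nchar(s$link1) +
      nchar(if (class == "D-armless") s$d_absent else s$d_arm) +
      nchar(s$link2)
  }
  offset <- as.integer(before_ac + nchar(s$ac5) + 2 + 1)
  list(sequence = seq, anticodon_offset = offset, class = class)
}

# Default per-tRNA class assignment (study-genome split: 8/8/5/1) and
# anticodons.
TRNA_CLASS_DEFAULT <- c(
  trnA = "full", trnH = "full", trnI = "full", trnL1 = "full",
  trnL2 = "full", trnM = "full", trnK = "full", trnV = "full",
  trnR = "T-armless", trnD = "T-armless", trnE = "T-armless",
  trnG = "T-armless", trnF = "T-armless", trnP = "T-armless",
  trnT = "T-armless", trnW = "T-armless",
  trnN = "D-armless", trnQ = "D-armless", trnS1 = "D-armless",
  trnS2 = "D-armless", trnY = "D-armless",
  trnC = "minimal")

# Codon frequencies ------------------------------------------------------------

#' Default codon frequency table for simulation
#'
#' Sense-codon sampling frequencies derived from the packaged study
#' codon-usage counts (stop codons excluded, counts normalized).
#'
#' @param code A [mito_genetic_code()].
#' @return Named numeric vector over sense codons summing to 1.
#' @export
default_codon_freqs <- function(code = mito_genetic_code()) {
  tab <- puto_codon_counts(code = code)
  cnt <- as.numeric(tab[code$sense])
  stats::setNames(cnt / sum(cnt), code$sense)
}

sample_codons <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Simulation configuration ------------------------------------------------------

#' Simulation configuration
#'
#' Assembles (and defaults) the configuration consumed by
#' [simulate_mitogenome()]. Defaults mirror the study genome: 18,830 bp
#' circular genome at 90.7% A+T, the study's 37-gene order and protein /
#' rRNA gene lengths, 15 overlaps, 14 spacers, two control regions, and the
#' 8/8/5/1 tRNA cloverleaf class split.
#'
#' @param seed Integer seed; one derived stream per sub-generator.
#' @param genome_length Genome length in bp.
#' @param at_content Target whole-genome A+T fraction.
#' @param codon_freqs Sense-codon sampling frequencies.
#' @param trna_classes Named character vector tRNA gene -> class.
#' @param code A [mito_genetic_code()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, genome_length = 18830, at_content = 0.907,
                       codon_freqs = NULL, trna_classes = TRNA_CLASS_DEFAULT,
                       code = mito_genetic_code()) {
  stopifnot(at_content >= 0, at_content <= 1, genome_length > 0)
  if (is.null(codon_freqs)) codon_freqs <- default_codon_freqs(code)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 at_content = at_content, codon_freqs = codon_freqs,
                 trna_classes = trna_classes, code = code),
            class = "sim_config")
}

# The default layout: the study gene order with study PCG/rRNA lengths,
# template-determined tRNA lengths, and a junction profile realizing 15
# overlaps / 14 spacers / 2 control regions. Overlaps are assigned so that
# content ownership (PCG > tRNA > rRNA > background) never corrupts what a
# later pipeline stage must recover: no protein-protein overlaps, and
# overlaps where a tRNA is the non-owning party are capped at 7 bp so its
# D-/T-arm windows stay clean.
default_sim_layout <- function(config) {
  ann <- puto_annotation()
  f <- ann$features
  ord <- f$gene
  # spacer AFTER each gene, in order (last entry = wrap control region,
  # resized below to meet genome_length)
  spacer_after <- c(
    COI = 8, trnL2 = 2, trnD = 0, ATP8 = 0, ATP6 = 31, COIII = -7,
    trnA = -4, trnR = 9, trnN = -3, trnE = -3, trnF = 21, trnH = -2,
    ND6 = 2, trnS1 = 27, trnQ = 12, ND1 = -1, trnL1 = -1, lrRNA = 0,
    trnV = 51, trnI = -2, trnM = 0, ND2 = -2, trnW = -2, trnY = 72,
    COII = 1, trnK = 37, trnG = -3, ND3 = -5, trnS2 = 21, ND5 = 0,
    ND4 = 0, ND4L = -7, trnT = -2, trnP = -7, trnC = 14, cytb = 2350,
    srRNA = NA)
  lens <- integer(length(ord)); names(lens) <- ord
  anticodons <- stats::setNames(f$anticodon, f$gene)
  templates <- list()
  for (g in ord) {
    cls <- feature_class_of(g)
    if (cls == "tRNA") {
      tpl <- trna_template(config$trna_classes[[g]],
                           anticodon = anticodons[[g]])
      templates[[g]] <- tpl
      lens[g] <- nchar(tpl$sequence)
    } else {
      lens[g] <- gene_length(f$start[f$gene == g], f$end[f$gene == g],
                             ann$genome_length)
    }
  }
  fixed_span <- sum(lens) + sum(spacer_after[-length(spacer_after)])
  wrap_cr <- config$genome_length - fixed_span
  if (wrap_cr < 1000) {
    stop("infeasible packing: genes + spacers span ", fixed_span,
         " bp, leaving ", wrap_cr, " bp for the wrap control region")
  }
  spacer_after["srRNA"] <- wrap_cr
  list(order = ord, lengths = lens, spacer_after = spacer_after,
       strands = stats::setNames(f$strand, f$gene),
       start_codons = stats::setNames(f$start_codon, f$gene),
       anticodons = anticodons, templates = templates)
}

#' Simulate an annotated mitogenome with ground truth
#'
#' Builds a circular genome realizing the configured gene order, geometry
#' and composition: protein-coding genes are sampled codon-by-codon from
#' the configured frequency table (ATN start, TAA stop, no internal stops),
#' tRNAs are written from class templates, rRNA / control-region /
#' background positions are drawn i.i.d. at a rate chosen so the
#' whole-genome A+T matches the target in expectation. Overlaps are
#' realized at annotation level with content ownership PCG > tRNA > rRNA,
#' so every downstream stage recovers its ground-truth quantity.
#'
#' @param config A [sim_config()].
#' @return List with `record` (a `sequence_record`), `annotation` (a
#'   `mito_annotation`) and `truth` (list: per-junction geometry, tRNA
#'   classes, per-gene CDS sequences, gene order, targets).
#' @export
simulate_mitogenome <- function(config = sim_config()) {
  layout <- default_sim_layout(config)
  L <- config$genome_length
  ord <- layout$order
  n <- length(ord)
  # coordinates
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + layout$lengths[[ord[i]]] - 1L
    pos <- end[i] + 1L + as.integer(layout$spacer_after[[ord[i]]])
  }
  if (end[n] > L) stop("infeasible packing: features exceed genome length")

  cls <- feature_class_of(ord)
  # expected A+T bookkeeping to hit the whole-genome target
  freqs <- config$codon_freqs
  at_per_codon <- vapply(names(freqs), function(cd)
    sum(strsplit(cd, "")[[1]] %in% c("A", "T")), numeric(1))
  pcg_len <- sum(layout$lengths[cls == "PCG"])
  at_pcg <- sum(freqs * at_per_codon) / 3 * pcg_len
  trna_at <- vapply(layout$templates, function(t) {
    sum(strsplit(t$sequence, "")[[1]] %in% c("A", "T"))
  }, numeric(1))
  trna_len_eff <- sum(vapply(layout$templates, function(t)
    nchar(t$sequence), numeric(1)))
  n_rest <- L - pcg_len - trna_len_eff
  at_rest_rate <- (config$at_content * L - at_pcg - sum(trna_at)) / n_rest
  at_rest_rate <- min(1, max(0, at_rest_rate))

  genome <- with_seed(sub_seed(config$seed, "background"), {
    sample(c("A", "T", "G", "C"), L, replace = TRUE,
           prob = c(at_rest_rate / 2, at_rest_rate / 2,
                    (1 - at_rest_rate) / 2, (1 - at_rest_rate) / 2))
  })

  put_segment <- function(genome, s, e, chars) {
    genome[s:e] <- chars
    genome
  }

  # rRNAs (random at the background rate already in place: keep background)
  # tRNAs from templates (coordinate order; later writes win)
  for (i in which(cls == "tRNA")) {
    g <- ord[i]
    tpl <- layout$templates[[g]]$sequence
    chars <- strsplit(if (layout$strands[[g]] == "N") revcomp(tpl) else tpl,
                      "")[[1]]
    genome <- put_segment(genome, start[i], end[i], chars)
  }
  # PCGs last: they own all their span
  cds_truth <- list()
  internal_freqs <- freqs[setdiff(names(freqs), config$code$stops)]
  for (i in which(cls == "PCG")) {
    g <- ord[i]
    len <- layout$lengths[[ord[i]]]
    n_cod <- len / 3
    stopifnot(len %% 3 == 0)
    startc <- layout$start_codons[[g]]
    if (is.na(startc)) startc <- "ATT"
    body <- with_seed(sub_seed(config$seed, paste0("pcg_", g)), {
      sample_codons(n_cod - 2, internal_freqs)
    })
    cds <- paste0(c(startc, body, "TAA"), collapse = "")
    cds_truth[[g]] <- cds
    chars <- strsplit(if (layout$strands[[g]] == "N") revcomp(cds) else cds,
                      "")[[1]]
    genome <- put_segment(genome, start[i], end[i], chars)
  }
  residues <- paste0(genome, collapse = "")

  # anticodon genome coordinates from template offsets
  ac_start <- integer(n); ac_end <- integer(n)
  for (i in seq_len(n)) {
    g <- ord[i]
    if (cls[i] == "tRNA") {
      off <- layout$templates[[g]]$anticodon_offset
      if (layout$strands[[g]] == "J") {
        ac_start[i] <- start[i] + off - 1L
      } else {
        ac_start[i] <- end[i] - off - 1L  # so that end - ac_end + 1 == off
      }
      ac_end[i] <- ac_start[i] + 2L
    } else {
      ac_start[i] <- NA_integer_; ac_end[i] <- NA_integer_
    }
  }

  feats <- data.frame(
    gene = ord, strand = unname(layout$strands[ord]),
    start = start, end = end, wraps_origin = FALSE,
    anticodon = unname(layout$anticodons[ord]),
    anticodon_start = ac_start, anticodon_end = ac_end,
    start_codon = ifelse(cls == "PCG", unname(layout$start_codons[ord]),
                         NA_character_),
    stop_codon = ifelse(cls == "PCG", "TAA", NA_character_),
    stringsAsFactors = FALSE)
  ann <- mito_annotation(feats, genome_length = L, topology = "circular")
  record <- new_sequence_record(
    sprintf("synthetic_mitogenome_seed%d", config$seed), residues,
    "circular")

  sp <- layout$spacer_after
  sp_num <- as.numeric(sp)
  truth <- list(
    config = config,
    genome_length = L,
    at_content_target = config$at_content,
    n_features = n,
    n_trna = sum(cls == "tRNA"), n_pcg = sum(cls == "PCG"),
    n_rrna = sum(cls == "rRNA"),
    n_overlaps = sum(sp_num < 0),
    overlap_lengths = -sp_num[sp_num < 0],
    n_spacers = sum(sp_num > 0 & sp_num < 1000),
    spacer_lengths = sp_num[sp_num > 0 & sp_num < 1000],
    control_region_lengths = sp_num[sp_num >= 1000],
    trna_classes = vapply(layout$templates, `[[`, "", "class"),
    trna_class_counts = table(factor(
      vapply(layout$templates, `[[`, "", "class"),
      levels = c("full", "T-armless", "D-armless", "minimal"))),
    cds = cds_truth,
    gene_order = gene_order(ifelse(layout$strands[ord] == "N",
                                   paste0("-", ord), ord),
                            taxon = record$id))
  list(record = record, annotation = ann, truth = truth)
}

# Codon-pair evolution ----------------------------------------------------------

#' Simulate a diverged codon-sequence pair under selection strength omega
#'
#' Draws an ancestor codon sequence from the configured frequencies, then
#' evolves a descendant along a branch of length `t` under a
#' continuous-time single-nucleotide codon model: each position mutates at
#' a base rate of 1 per unit time, transitions are scaled by `kappa`,
#' nonsynonymous changes by `omega`, and mutations to stop codons are
#' rejected (rate 0). `t` is therefore the expected number of attempted
#' neutral substitutions per site.
#'
#' @param length_codons Number of codons.
#' @param omega Nonsynonymous/synonymous rate ratio (> 0; 0 allowed:
#'   purely synonymous evolution).
#' @param t Branch length (> 0; 0 yields an identical pair).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @param code A [mito_genetic_code()].
#' @param codon_freqs Ancestor sampling frequencies (defaults to the study
#'   table).
#' @return List with `ancestor` and `descendant` CDS strings (no stop
#'   codons) plus the realized substitution counts.
#' @export
evolve_codon_pair <- function(length_codons, omega, t, kappa = 2, seed = 1,
                              code = mito_genetic_code(),
                              codon_freqs = NULL) {
  stopifnot(length_codons > 0, omega >= 0, t >= 0)
  if (is.null(codon_freqs)) codon_freqs <- default_codon_freqs(code)
  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  n_sub <- 0L
  with_seed(sub_seed(seed, "codon_pair"), {
    anc <- sample_codons(length_codons, codon_freqs)
    des <- anc
    for (k in seq_len(length_codons)) {
      time <- 0
      repeat {
        cur <- des[k]
        aa <- code$map[[cur]]
        # single-nucleotide neighbor rates
        targets <- character(0); rates <- numeric(0)
        bc <- strsplit(cur, "")[[1]]
        for (p in 1:3) {
          for (nt in setdiff(c("A", "C", "G", "T"), bc[p])) {
            nb <- bc; nb[p] <- nt
            nbc <- paste0(nb, collapse = "")
            if (nbc %in% code$stops) next
            r <- (1 / 3) * (if (is_transition(bc[p], nt)) kappa else 1) *
              (if (code$map[[nbc]] == aa) 1 else omega)
            if (r > 0) { targets <- c(targets, nbc); rates <- c(rates, r) }
          }
        }
        total <- sum(rates)
        if (total == 0) break
        time <- time + stats::rexp(1, total)
        if (time > t) break
        des[k] <- sample(targets, 1, prob = rates)
        n_sub <- n_sub + 1L
      }
    }
    list(ancestor = paste0(anc, collapse = ""),
         descendant = paste0(des, collapse = ""),
         n_substitutions = n_sub)
  })
}

# Gene-order perturbation ---------------------------------------------------------

#' Apply random rearrangement events to a gene order
#'
#' Applies `k_events` random events, each a transposition (a contiguous
#' block moved to another position) or an inversion (a contiguous block
#' reversed with signs flipped), chosen per `event_mix`. An event log
#' sufficient to verify each change is returned.
#'
#' @param order A `gene_order`.
#' @param k_events Number of events (0 = identity).
#' @param event_mix Named probabilities for `transposition` and `inversion`.
#' @param seed Integer seed.
#' @param max_block Maximum block length per event.
#' @return List with `order` (the perturbed `gene_order`) and `events`
#'   (data.frame type/from/length/to).
#' @export
perturb_gene_order <- function(order, k_events,
                               event_mix = c(transposition = 0.5,
                                             inversion = 0.5),
                               seed = 1, max_block = 3) {
  stopifnot(k_events >= 0)
  genes <- order$genes; signs <- order$signs
  events <- list()
  with_seed(sub_seed(seed, "perturb"), {
    for (e in seq_len(k_events)) {
      n <- length(genes)
      type <- sample(names(event_mix), 1, prob = event_mix)
      blen <- sample(seq_len(min(max_block, n - 2)), 1)
      from <- sample(n - blen + 1, 1)
      idx <- from:(from + blen - 1)
      if (type == "inversion") {
        genes[idx] <- rev(genes[idx])
        signs[idx] <- rev(-signs[idx])
        to <- from
      } else {
        bg <- genes[idx]; bs <- signs[idx]
        genes <- genes[-idx]; signs <- signs[-idx]
        to <- sample(length(genes) + 1, 1)
        genes <- append(genes, bg, after = to - 1)
        signs <- append(signs, bs, after = to - 1)
      }
      events[[e]] <- data.frame(type = type, from = from, length = blen,
                                to = to, stringsAsFactors = FALSE)
    }
    list(order = structure(list(taxon = order$taxon, genes = genes,
                                signs = signs), class = "gene_order"),
         events = if (length(events)) do.call(rbind, events) else
           data.frame(type = character(), from = integer(),
                      length = integer(), to = integer()))
  })
}

#' Simulate a codon-usage panel along an AT-content gradient
#'
#' Generates one CDS set per requested A+T level, sampling codons with
#' per-position nucleotide probabilities P(A) = P(T) = at/2,
#' P(G) = P(C) = (1-at)/2 restricted to sense codons. Higher AT
#' concentrates usage on AT-rich codons within each family, reproducing
#' the empirical pattern that AT-rich mitogenomes show stronger codon bias
#' (lower ENC, higher CBI).
#'
#' @param at_values Vector of target A+T fractions.
#' @param n_codons Codons per simulated genome.
#' @param seed Integer seed.
#' @param code A [mito_genetic_code()].
#' @return data.frame with columns `at`, `enc`, `cbi`, `gc`, `gc3`.
#' @export
simulate_codon_panel <- function(at_values, n_codons = 20000, seed = 1,
                                 code = mito_genetic_code()) {
  rows <- lapply(seq_along(at_values), function(i) {
    at <- at_values[i]
    p_nt <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
    pr <- vapply(code$sense, function(cd) {
      prod(p_nt[strsplit(cd, "")[[1]]])
    }, numeric(1))
    pr <- pr / sum(pr)
    cods <- with_seed(sub_seed(seed, paste0("panel_", i)), {
      sample(code$sense, n_codons, replace = TRUE, prob = pr)
    })
    tab <- codon_count_table(table(cods), code = code)
    cbind(data.frame(at = at), codon_bias_metrics(tab))
  })
  do.call(rbind, rows)
}
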