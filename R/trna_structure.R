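# Heuristic cloverleaf-completeness classification of mitochondrial tRNAs.
# Mitochondrial tRNAs, especially in AT-rich hemipteran genomes, routinely
# lack the D (dihydrouridine) arm, the T (T-psi-C) arm, or both; the
# classifier anchors on the annotated anticodon, then looks for the
# anticodon stem, the acceptor stem between the molecule's ends, and
# D-/T-arm hairpins in the windows 5' and 3' of the anticodon arm. It is a
# transparent heuristic for completeness classes, not a covariance-model
# tRNA finder.

is_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  wc
}

# Longest hairpin (>= min_pairs stem, loop in loop_range) fully inside
# window positions [from, to] of chars b. Returns stem length (0 = none).
find_hairpin <- function(b, from, to, min_pairs, loop_range = c(3, 11),
                         allow_gu = TRUE) {
  if (is.na(from) || is.na(to) || to - from + 1 < 2 * min_pairs + loop_range[1]) {
    return(0L)
  }
  best <- 0L
  for (a in from:(to - 2 * min_pairs - loop_range[1] + 1)) {
    for (l in loop_range[1]:loop_range[2]) {
      smax <- (to - a + 1 - l) %/% 2
      if (smax < min_pairs) next
      for (s in smax:min_pairs) {
        end2 <- a + 2 * s + l - 1
        if (end2 > to) next
        i <- 0:(s - 1)
        ok <- all(is_pair(b[a + i], b[end2 - i], allow_gu))
        if (ok && s > best) best <- s
        if (ok) break  # longest stem at this (a, l) found
      }
    }
  }
  best
}

#' Detect tRNA arms and classify cloverleaf completeness
#'
#' Anchored on the annotated anticodon, searches for: the anticodon stem
#' (complementary pairs flanking the 7-nt anticodon loop); the acceptor
#' stem (pairs between the 5' and 3' ends, allowing up to 4 nt of unpaired
#' 3' overhang for the discriminator/CCA); a D-arm hairpin 5' of the
#' anticodon arm; and a T-arm hairpin 3' of it. G-U wobble counts as a
#' pair. The completeness class is `"full"`, `"D-armless"`, `"T-armless"`,
#' or `"minimal"` (both side arms missing).
#'
#' @param sequence tRNA gene sequence, sense strand, 5'->3' (character).
#' @param anticodon_start 1-based position of the anticodon's first
#'   nucleotide within `sequence`. When `NA`, the center of the sequence is
#'   assumed with a warning.
#' @param min_stem_pairs Minimum complementary pairs for the anticodon, D
#'   and T stems.
#' @param min_acceptor_pairs Minimum pairs for the acceptor stem.
#' @param loop_range Allowed D-/T-loop sizes (nt).
#' @param allow_gu Count G-U wobble as a pair.
#' @return A `trna_model`: list with fields `length`, `anticodon`,
#'   `acceptor_pairs`, `anticodon_stem`, `d_arm` / `t_arm` (stem length, 0
#'   = absent), the presence flags, and `class`.
#' @export
detect_arms <- function(sequence, anticodon_start = NA,
                        min_stem_pairs = 3, min_acceptor_pairs = 4,
                        loop_range = c(3, 11), allow_gu = TRUE) {
  s <- normalize_codons(sequence)
  b <- strsplit(s, "")[[1]]
  L <- length(b)
  if (L < 20) stop("sequence too short to be a tRNA gene: ", L, " nt")
  if (is.na(anticodon_start)) {
    warning("no anticodon position supplied; assuming center of sequence",
            call. = FALSE)
    anticodon_start <- (L - 2) %/% 2
  }
  if (anticodon_start < 1 || anticodon_start + 2 > L) {
    stop("anticodon span outside sequence")
  }
  loop_start <- max(1, anticodon_start - 2)
  loop_end <- min(L, anticodon_start + 4)
  # anticodon stem: contiguous pairs flanking the loop
  ac_stem <- 0L
  i <- 1
  while (loop_start - i >= 1 && loop_end + i <= L &&
         is_pair(b[loop_start - i], b[loop_end + i], allow_gu) && i <= 7) {
    ac_stem <- ac_stem + 1L
    i <- i + 1
  }
  # acceptor stem: 5' end vs 3' end with 0-4 nt 3' overhang
  acc_best <- 0L; acc_overhang <- 0L
  for (h in 0:4) {
    run <- 0L
    for (i in seq_len(7)) {
      j <- L - h + 1 - i
      if (j <= i) break
      if (is_pair(b[i], b[j], allow_gu)) run <- run + 1L else break
    }
    if (run > acc_best) { acc_best <- run; acc_overhang <- h }
  }
  ac5 <- loop_start - ac_stem  # first position of the anticodon arm
  ac3 <- loop_end + ac_stem    # last position of the anticodon arm
  acc5_end <- if (acc_best >= min_acceptor_pairs) acc_best else
    min(min_acceptor_pairs, max(0, ac5 - 1))
  d_stem <- find_hairpin(b, acc5_end + 1, ac5 - 1, min_stem_pairs,
                         loop_range, allow_gu)
  t_from <- ac3 + 1
  t_to <- L - acc_overhang - max(acc_best, min_acceptor_pairs)
  t_stem <- find_hairpin(b, t_from, t_to, min_stem_pairs, loop_range,
                         allow_gu)
  d_present <- d_stem >= min_stem_pairs
  t_present <- t_stem >= min_stem_pairs
  cls <- if (d_present && t_present) "full" else
    if (!d_present && t_present) "D-armless" else
    if (d_present && !t_present) "T-armless" else "minimal"
  structure(list(length = L,
                 anticodon = paste0(b[anticodon_start:(anticodon_start + 2)],
                                    collapse = ""),
                 acceptor_pairs = acc_best,
                 acceptor_present = acc_best >= min_acceptor_pairs,
                 anticodon_stem = ac_stem,
                 anticodon_stem_present = ac_stem >= min_stem_pairs,
                 d_arm = d_stem, d_present = d_present,
                 t_arm = t_stem, t_present = t_present,
                 class = cls),
            class = "trna_model")
}

#' @export
print.trna_model <- function(x, ...) {
  cat("<trna_model> ", x$length, " nt, anticodon ", x$anticodon,
      ", class ", x$class, "\n", sep = "")
  cat(sprintf("  acceptor %d pairs | AC stem %d | D stem %d | T stem %d\n",
              x$acceptor_pairs, x$anticodon_stem, x$d_arm, x$t_arm))
  invisible(x)
}

#' Classify all tRNA genes of an annotated genome
#'
#' Extracts each annotated tRNA on its sense strand (so classification is
#' strand-invariant) and runs [detect_arms()] using the annotated anticodon
#' location, converted from genome coordinates to a position within the
#' gene.
#'
#' @param annotation A `mito_annotation`.
#' @param residues Genome sequence.
#' @param ... Passed to [detect_arms()] (thresholds).
#' @return List with `table` (data.frame gene/length/anticodon/class) and
#'   `summary` (named counts for full, T-armless, D-armless, minimal).
#' @export
classify_trnas <- function(annotation, residues, ...) {
  f <- annotation$features[annotation$features$feature_class == "tRNA", ,
                           drop = FALSE]
  classes <- c("full", "T-armless", "D-armless", "minimal")
  if (nrow(f) == 0) {
    return(list(table = data.frame(gene = character(), length = integer(),
                                   anticodon = character(),
                                   class = character()),
                summary = stats::setNames(rep(0L, 4), classes)))
  }
  rows <- lapply(seq_len(nrow(f)), function(i) {
    seq <- feature_sequence(annotation, residues, f$gene[i])
    L <- nchar(seq)
    # genome coords -> position within the sense-strand gene sequence
    ac_pos <- if (is.na(f$anticodon_start[i])) NA_integer_ else {
      if (f$strand[i] == "J") f$anticodon_start[i] - f$start[i] + 1L
      else f$end[i] - f$anticodon_end[i] + 1L
    }
    model <- detect_arms(seq, anticodon_start = ac_pos, ...)
    data.frame(gene = f$gene[i], length = L, anticodon = model$anticodon,
               class = model$class, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  summary <- vapply(classes, function(cl) sum(tab$class == cl), integer(1))
  list(table = tab, summary = summary)
}
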