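#' Codon count table
#'
#' Builds the per-codon count table underlying every codon-usage metric.
#' `count_codons()` counts codons (stop codons included: stop usage is
#' tabulated and given RSCU like any other family) over one or more CDS
#' sequences supplied on their sense strands; `codon_count_table()` wraps an
#' existing named count vector (e.g. a published codon-usage table).
#'
#' @param cds Character vector of sense-strand CDS sequences, each of length
#'   divisible by 3. RNA spelling accepted.
#' @param code A [mito_genetic_code()].
#' @param genes Optional gene labels (for warnings).
#' @return A `codon_count_table`: named integer vector over all 64 codons
#'   (DNA spelling) with attributes `code` and `source`.
#' @export
count_codons <- function(cds, code = mito_genetic_code(), genes = NULL) {
  counts <- stats::setNames(integer(length(code$map)), names(code$map))
  if (is.null(genes)) genes <- paste0("cds", seq_along(cds))
  for (i in seq_along(cds)) {
    s <- normalize_codons(cds[i])
    if (nchar(s) %% 3 != 0) {
      stop("CDS length not divisible by 3: ", genes[i])
    }
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    bad <- !(cod %in% names(counts))
    if (any(bad)) stop("non-ACGT codon in ", genes[i], ": ",
                       paste(unique(cod[bad]), collapse = ", "))
    internal_stop <- cod[-length(cod)] %in% code$stops
    if (any(internal_stop)) {
      warning("internal stop codon(s) in ", genes[i], " at codon ",
              paste(which(internal_stop), collapse = ", "), call. = FALSE)
    }
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  codon_count_table(counts, code = code)
}

#' @rdname count_codons
#' @param counts Named numeric vector of codon counts (DNA or RNA spelling);
#'   codons absent from the vector count 0.
#' @export
codon_count_table <- function(counts, code = mito_genetic_code()) {
  nm <- normalize_codons(names(counts))
  full <- stats::setNames(numeric(length(code$map)), names(code$map))
  unknown <- setdiff(nm, names(full))
  if (length(unknown)) stop("unknown codons: ", paste(unknown, collapse = ", "))
  full[nm] <- full[nm] + as.numeric(counts)
  if (any(full < 0)) stop("negative codon counts")
  structure(full, code = code, class = "codon_count_table")
}

#' @export
print.codon_count_table <- function(x, ...) {
  code <- attr(x, "code")
  cat("<codon_count_table> ", sum(x), " codons under code ", code$id,
      " (", sum(x[code$stops]), " stops)\n", sep = "")
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon i in a synonymous family of size k with family total N,
#' RSCU_i = n_i * k / N: the observed count relative to the expectation
#' under uniform usage within the family. Families with N = 0 get `NA`.
#' The stop codons form their own 2-codon family under the mitochondrial
#' codes and receive RSCU values like any amino-acid family.
#'
#' @param table A `codon_count_table`.
#' @param digits Decimals for the `rscu_rounded` column (reporting
#'   convention: 2).
#' @return data.frame with columns `codon` (RNA spelling), `amino_acid`,
#'   `family_size`, `count`, `rscu` (exact), `rscu_rounded`.
#' @export
rscu <- function(table, digits = 2) {
  code <- attr(table, "code")
  rows <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    k <- length(fam)
    N <- sum(table[fam])
    val <- if (N == 0) rep(NA_real_, k) else as.numeric(table[fam]) * k / N
    data.frame(codon = codon_to_rna(fam), amino_acid = aa, family_size = k,
               count = as.numeric(table[fam]), rscu = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rscu_rounded <- round_half_up(out$rscu, digits)
  rownames(out) <- NULL
  out
}

# Per-family homozygosity F-hat = (n * sum p^2 - 1) / (n - 1); NA when n < 2.
family_homozygosity <- function(table, fam) {
  n <- sum(table[fam])
  if (n < 2) return(NA_real_)
  p <- as.numeric(table[fam]) / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC generalized to an arbitrary synonymous-family structure
#' (required for mitochondrial codes, where family sizes are 2, 4, 6 and 8).
#' Per family the homozygosity F-hat = (n * sum p^2 - 1)/(n - 1) is
#' computed; F-hat is averaged within each family-size class, and
#' ENC = sum over classes of N_c / Fbar_c, capped at the number of sense
#' codons. Stop codons are excluded (ENC is amino-acid based). Families with
#' n < 2 are imputed with their size class's mean F-hat; a size class with
#' no computable family is dropped and ENC rescaled by the full-code
#' expectation of that class (codons of the class added as k_c * N_c /
#' ENC-contribution is unavailable, so the cap keeps the value in range).
#'
#' @param table A `codon_count_table`.
#' @return ENC value in `[20, n_sense]` (for the invertebrate mitochondrial
#'   code, `[20, 62]`), or `NA` when nothing is computable.
#' @export
enc <- function(table) {
  code <- attr(table, "code")
  fams <- code$families[names(code$families) != "*"]
  sizes <- lengths(fams)
  fhat <- vapply(fams, function(fam) family_homozygosity(table, fam),
                 numeric(1))
  total <- 0
  dropped_codons <- 0
  for (k in sort(unique(sizes))) {
    idx <- sizes == k
    vals <- fhat[idx]
    if (all(is.na(vals))) {
      dropped_codons <- dropped_codons + sum(k * sum(idx))
      next
    }
    fbar <- mean(vals, na.rm = TRUE)  # n<2 families imputed with class mean
    if (fbar <= 0) fbar <- 1 / k      # guard: cannot exceed uniform limit
    total <- total + sum(idx) / fbar
  }
  if (total == 0) return(NA_real_)
  n_sense <- length(code$sense)
  if (dropped_codons > 0) {
    # rescale so the reported value refers to the full sense-codon space
    total <- total * n_sense / (n_sense - dropped_codons)
  }
  min(total, n_sense)
}

#' Codon bias index (CBI)
#'
#' CBI = (N_opt - N_rand) / (N_tot - N_rand) with N_rand = sum over families
#' of N_family / k_family: the excess usage of "optimal" codons beyond the
#' uniform expectation. 0 for uniform usage, 1 when only optimal codons are
#' used. By default the optimal set is derived from the analyzed table
#' itself (each family's most frequent codon), the usual "all genes" mode.
#' Stop codons are excluded.
#'
#' @param table A `codon_count_table`.
#' @param optimal_codons Optional character vector of optimal codons (one
#'   per family; DNA or RNA spelling).
#' @return CBI value, `NA` if no codons counted.
#' @export
cbi <- function(table, optimal_codons = NULL) {
  code <- attr(table, "code")
  fams <- code$families[names(code$families) != "*"]
  if (!is.null(optimal_codons)) optimal_codons <- normalize_codons(optimal_codons)
  n_tot <- 0; n_opt <- 0; n_rand <- 0
  for (fam in fams) {
    N <- sum(table[fam])
    if (N == 0) next
    opt <- if (is.null(optimal_codons)) {
      fam[which.max(table[fam])]
    } else {
      intersect(fam, optimal_codons)
    }
    n_tot <- n_tot + N
    n_opt <- n_opt + sum(table[opt])
    n_rand <- n_rand + length(opt) * N / length(fam)
  }
  if (n_tot == 0 || n_tot == n_rand) return(NA_real_)
  (n_opt - n_rand) / (n_tot - n_rand)
}

#' GC content of a codon table
#'
#' G+C fraction over all codon positions and over third positions only,
#' computed from the codon strings weighted by their counts. Stop codons are
#' excluded, matching the ENC/CBI convention.
#'
#' @param table A `codon_count_table`.
#' @return Named numeric vector `c(gc = ..., gc3 = ...)`, fractions in
#'   `[0, 1]`.
#' @export
gc_content <- function(table) {
  code <- attr(table, "code")
  sense <- code$sense
  cnt <- as.numeric(table[sense])
  if (sum(cnt) == 0) return(c(gc = NA_real_, gc3 = NA_real_))
  gc_all <- vapply(sense, function(cd)
    sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
  gc_3 <- vapply(sense, function(cd)
    as.numeric(substr(cd, 3, 3) %in% c("G", "C")), numeric(1))
  c(gc = sum(cnt * gc_all) / (3 * sum(cnt)),
    gc3 = sum(cnt * gc_3) / sum(cnt))
}

#' Codon-bias metrics for a CDS set
#'
#' One-call wrapper computing ENC, CBI, GC and GC3 from sense-strand CDS
#' sequences (or an existing count table).
#'
#' @param x Character vector of CDS sequences or a `codon_count_table`.
#' @param code A [mito_genetic_code()] (ignored when `x` is already a table).
#' @return One-row data.frame with columns `enc`, `cbi`, `gc`, `gc3`.
#' @export
codon_bias_metrics <- function(x, code = mito_genetic_code()) {
  tab <- if (inherits(x, "codon_count_table")) x else count_codons(x, code)
  g <- gc_content(tab)
  data.frame(enc = enc(tab), cbi = cbi(tab), gc = g[["gc"]],
             gc3 = g[["gc3"]])
}

#' Correlations among codon-bias metrics across genomes
#'
#' Pairwise correlations of ENC, CBI, GC and GC3 across a panel of genomes:
#' ENC~GC, ENC~GC3, CBI~GC, CBI~GC3 and ENC~CBI, with a sign summary. The
#' default method is Spearman's rank correlation (the relationships are
#' monotone rather than linear across AT-content gradients); Pearson is
#' available.
#'
#' @param metrics data.frame with columns `enc`, `cbi`, `gc`, `gc3`, one row
#'   per genome (3 or more rows).
#' @param method `"spearman"` or `"pearson"`.
#' @return data.frame with columns `pair`, `rho`, `sign` (`"+"`, `"-"`, or
#'   `NA` for undefined, e.g. constant input).
#' @export
bias_correlations <- function(metrics, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(nrow(metrics) >= 3)
  pairs <- list(c("enc", "gc"), c("enc", "gc3"), c("cbi", "gc"),
                c("cbi", "gc3"), c("enc", "cbi"))
  rows <- lapply(pairs, function(p) {
    x <- metrics[[p[1]]]; y <- metrics[[p[2]]]
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      suppressWarnings(stats::cor(x, y, method = method))
    data.frame(pair = paste(toupper(p[1]), toupper(p[2]), sep = "~"),
               rho = rho,
               sign = if (is.na(rho)) NA_character_ else
                 if (rho > 0) "+" else if (rho < 0) "-" else "0",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
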