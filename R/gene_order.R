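#' Signed circular gene orders
#'
#' A gene order is a circular sequence of signed gene labels: the sign
#' records orientation (`+`/no prefix = majority J strand, `-` = minority N
#' strand). `gene_order()` constructs one from signed labels like
#' `c("COI", "-trnY", ...)`.
#'
#' @param labels Character vector of signed gene labels (optional leading
#'   `-`).
#' @param taxon Optional taxon label.
#' @return A `gene_order`: list with `taxon`, `genes` (unsigned labels) and
#'   `signs` (+1/-1).
#' @export
gene_order <- function(labels, taxon = NA_character_) {
  labels <- unname(trimws(labels))
  stopifnot(length(labels) > 0)
  signs <- ifelse(startsWith(labels, "-"), -1L, 1L)
  genes <- sub("^[+-]", "", labels)
  if (anyDuplicated(genes)) {
    stop("duplicate gene labels in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(taxon = taxon, genes = genes, signs = signs),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order>", if (!is.na(x$taxon)) x$taxon else "", "(",
      length(x$genes), "genes ):\n")
  cat(" ", paste(format_signed(x), collapse = ","), "\n")
  invisible(x)
}

format_signed <- function(order) {
  paste0(ifelse(order$signs < 0, "-", ""), order$genes)
}

#' @export
length.gene_order <- function(x) length(x$genes)

#' Canonical rotation of a circular gene order
#'
#' Rotates the order to start at a fixed anchor gene in positive
#' orientation; if the anchor sits on the minority strand the whole order is
#' reflected (reversed with all signs flipped) first. Canonical forms make
#' rotation/reflection-equivalent circular orders compare equal.
#'
#' @param order A `gene_order`.
#' @param anchor Anchor gene label (default COI, present in every
#'   mitogenome).
#' @return A canonicalized `gene_order`.
#' @export
canonicalize <- function(order, anchor = "COI") {
  i <- match(anchor, order$genes)
  if (is.na(i)) stop("anchor gene absent from order: ", anchor)
  genes <- order$genes; signs <- order$signs
  if (signs[i] < 0) {
    genes <- rev(genes); signs <- rev(-signs)
    i <- match(anchor, genes)
  }
  if (i > 1) {
    idx <- c(i:length(genes), seq_len(i - 1))
    genes <- genes[idx]; signs <- signs[idx]
  }
  structure(list(taxon = order$taxon, genes = genes, signs = signs),
            class = "gene_order")
}

# Signed circular adjacency set; the adjacency x->y is identified with
# -y->-x, represented by whichever spelling sorts first.
adjacency_set <- function(order) {
  n <- length(order$genes)
  lab <- format_signed(order)
  neg <- function(s) ifelse(startsWith(s, "-"), sub("^-", "", s),
                            paste0("-", s))
  out <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fwd <- paste(lab[i], lab[j], sep = "|")
    rev <- paste(neg(lab[j]), neg(lab[i]), sep = "|")
    out[i] <- min(fwd, rev)
  }
  out
}

#' Breakpoint distance between circular signed gene orders
#'
#' The number of signed adjacencies (x followed by y, identified with -y
#' followed by -x) present in one order but not the other. When the label
#' sets differ, the comparison is restricted to the shared labels with a
#' warning. A pseudometric on circular signed orders: zero iff the orders
#' are equal up to rotation/reflection.
#'
#' @param a,b `gene_order` objects.
#' @return Non-negative integer distance.
#' @export
breakpoint_distance <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  if (length(shared) < length(a$genes) || length(shared) < length(b$genes)) {
    warning("orders have different label sets; restricting to ",
            length(shared), " shared labels", call. = FALSE)
    keep <- function(o) {
      i <- o$genes %in% shared
      structure(list(taxon = o$taxon, genes = o$genes[i],
                     signs = o$signs[i]), class = "gene_order")
    }
    a <- keep(a); b <- keep(b)
  }
  if (length(shared) == 0) stop("no shared gene labels")
  length(setdiff(adjacency_set(a), adjacency_set(b)))
}

#' Find a signed gene cluster in a circular order
#'
#' Searches for contiguous circular occurrences of a signed pattern (length
#' 2 or more). With `orientation_sensitive = TRUE` (default) the inverted
#' spelling of the pattern (reversed order, flipped signs) is also sought
#' and reported as an inverted occurrence.
#'
#' @param order A `gene_order`.
#' @param pattern Character vector of signed labels, e.g.
#'   `c("trnM", "ND2", "trnW")`.
#' @param orientation_sensitive Also match the reverse-complement pattern.
#' @return data.frame with columns `position` (1-based index of the match
#'   start in the order) and `orientation` (`"forward"`/`"inverted"`);
#'   zero rows when absent.
#' @export
find_cluster <- function(order, pattern, orientation_sensitive = TRUE) {
  pat <- gene_order(pattern)
  n <- length(order$genes)
  m <- length(pat$genes)
  stopifnot(m >= 2)
  if (m > n) return(data.frame(position = integer(), orientation = character()))
  lab <- format_signed(order)
  lab2 <- c(lab, lab)  # doubled for circular matching
  plab <- format_signed(pat)
  inv <- paste0(ifelse(rev(pat$signs) < 0, "", "-"), rev(pat$genes))
  hits <- list()
  for (i in seq_len(n)) {
    win <- lab2[i:(i + m - 1)]
    if (identical(win, plab)) {
      hits[[length(hits) + 1]] <- data.frame(position = i,
                                             orientation = "forward")
    } else if (orientation_sensitive && identical(win, inv)) {
      hits[[length(hits) + 1]] <- data.frame(position = i,
                                             orientation = "inverted")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), orientation = character()))
  }
  do.call(rbind, hits)
}

#' Scan gene-cluster patterns for group-diagnostic (apomorphic) states
#'
#' For each pattern and each taxon group, computes the fraction of group
#' members carrying the cluster (via [find_cluster()]). A pattern is
#' flagged `diagnostic` when it occurs in exactly one group and in no
#' member of any other group - the rearrangement analogue of a derived
#' character state; `fixed` additionally requires presence in every member
#' of that group.
#'
#' @param orders Named list of `gene_order` objects (names = taxa).
#' @param patterns Named list of signed-label character vectors.
#' @param groups Named character vector mapping taxon -> group label; taxa
#'   absent from `groups` are ignored.
#' @return List with `presence` (taxon x pattern logical matrix),
#'   `fractions` (group x pattern numeric matrix), and `diagnostic`
#'   (data.frame pattern/group/fraction/fixed for flagged patterns).
#' @export
apomorphy_scan <- function(orders, patterns, groups) {
  taxa <- intersect(names(orders), names(groups))
  if (length(unique(groups[taxa])) < 2) stop("need at least 2 groups")
  all_genes <- unique(unlist(lapply(orders, `[[`, "genes")))
  for (pn in names(patterns)) {
    pg <- sub("^[+-]", "", trimws(patterns[[pn]]))
    bad <- setdiff(pg, all_genes)
    if (length(bad)) stop("pattern ", pn, " references unknown gene label: ",
                          paste(bad, collapse = ", "))
  }
  presence <- sapply(names(patterns), function(pn) {
    vapply(taxa, function(tx)
      nrow(find_cluster(orders[[tx]], patterns[[pn]])) > 0, logical(1))
  })
  presence <- matrix(presence, nrow = length(taxa),
                     dimnames = list(taxa, names(patterns)))
  glab <- sort(unique(groups[taxa]))
  fractions <- t(vapply(glab, function(g) {
    colMeans(presence[groups[taxa] == g, , drop = FALSE])
  }, numeric(ncol(presence))))
  dimnames(fractions) <- list(glab, colnames(presence))
  diag_rows <- list()
  for (pn in colnames(fractions)) {
    pos <- fractions[, pn] > 0
    if (sum(pos) == 1) {
      g <- glab[pos]
      diag_rows[[length(diag_rows) + 1]] <- data.frame(
        pattern = pn, group = g, fraction = fractions[g, pn],
        fixed = fractions[g, pn] == 1, stringsAsFactors = FALSE)
    }
  }
  diagnostic <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(pattern = character(), group = character(),
               fraction = numeric(), fixed = logical())
  list(presence = presence, fractions = fractions, diagnostic = diagnostic)
}

#' Breakpoint-distance matrix and neighbor-joining tree
#'
#' `order_distance_matrix()` computes all pairwise breakpoint distances;
#' `nj_tree()` runs standard neighbor joining (via ape) on such a matrix,
#' clamping negative branch lengths to zero, and returns newick text.
#'
#' @param orders Named list of `gene_order` objects (3 or more).
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
order_distance_matrix <- function(orders) {
  stopifnot(length(orders) >= 3)
  nm <- names(orders)
  if (is.null(nm)) nm <- vapply(orders, `[[`, "", "taxon")
  n <- length(orders)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])
    }
  }
  d
}

#' @rdname order_distance_matrix
#' @param d Symmetric distance matrix with dimnames.
#' @param path Optional path; when given the newick text is written there.
#' @return `nj_tree()`: newick string (invisibly when writing to `path`).
#' @export
nj_tree <- function(d, path = NULL) {
  stopifnot(is.matrix(d), nrow(d) >= 3, isTRUE(all.equal(d, t(d))))
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read and write the gene-order exchange format
#'
#' One taxon per line: taxon label, whitespace, then comma-separated signed
#' gene labels (`-trnY` = minority strand). Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return `read_gene_orders()`: named list of `gene_order` objects.
#' @export
read_gene_orders <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  orders <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexpr("^\\S+", ln))
    rest <- trimws(sub("^\\S+", "", ln))
    gene_order(strsplit(rest, ",")[[1]], taxon = m)
  })
  stats::setNames(orders, vapply(orders, `[[`, "", "taxon"))
}

#' @rdname read_gene_orders
#' @param orders Named list of `gene_order` objects.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(names(orders), function(nm) {
    paste(nm, paste(format_signed(orders[[nm]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
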