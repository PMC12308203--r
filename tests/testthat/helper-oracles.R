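# Independent oracles and small generators used across the suite.

# Straight-line ENC oracle: per-family homozygosity, averaged per family
# size class, ENC = sum N_c / Fbar_c (no imputation path: callers must
# supply tables where every class has computable families).
oracle_enc <- function(counts, code) {
  fams <- code$families[names(code$families) != "*"]
  ks <- lengths(fams)
  F <- sapply(fams, function(fam) {
    n <- sum(counts[fam])
    if (n < 2) return(NA_real_)
    p <- counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  total <- 0
  for (k in unique(ks)) {
    total <- total + sum(ks == k) / mean(F[ks == k], na.rm = TRUE)
  }
  min(total, length(code$sense))
}

# Straight-line CBI oracle with per-family most-frequent codon as optimal.
oracle_cbi <- function(counts, code) {
  fams <- code$families[names(code$families) != "*"]
  n_tot <- 0; n_opt <- 0; n_rand <- 0
  for (fam in fams) {
    N <- sum(counts[fam])
    if (N == 0) next
    n_tot <- n_tot + N
    n_opt <- n_opt + max(counts[fam])
    n_rand <- n_rand + N / length(fam)
  }
  (n_opt - n_rand) / (n_tot - n_rand)
}

# Exhaustive path-enumeration oracle for NG86 difference counting: DFS over
# all single-nucleotide substitution paths from codon a to codon b of
# minimal length, excluding paths that visit a stop codon; equal-weight
# average of per-path synonymous/nonsynonymous step counts.
oracle_codon_diffs <- function(a, b, code) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  paths <- list()
  dfs <- function(cur, syn, nonsyn) {
    if (cur == b) {
      paths[[length(paths) + 1]] <<- c(syn = syn, nonsyn = nonsyn)
      return(invisible())
    }
    ca <- strsplit(cur, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    for (p in which(ca != cb)) {
      nx <- ca; nx[p] <- cb[p]
      nxt <- paste0(nx, collapse = "")
      if (nxt %in% code$stops && nxt != b) next
      if (nxt %in% code$stops) next
      step_syn <- code$map[[cur]] == code$map[[nxt]]
      dfs(nxt, syn + step_syn, nonsyn + !step_syn)
    }
  }
  dfs(a, 0, 0)
  if (length(paths) == 0) return(NULL)  # all paths stop-traversing
  Reduce(`+`, paths) / length(paths)
}

# Random codon count table where every family-size class is well observed.
random_codon_table <- function(seed, code, lambda = 30) {
  set.seed(seed)
  counts <- stats::setNames(stats::rpois(length(code$map), lambda) +
                              ifelse(seq_along(code$map) %% 3 == 0, 2L, 0L),
                            names(code$map))
  codon_count_table(counts, code = code)
}

# Random signed circular order over n generic labels.
random_order <- function(n = 20, taxon = NA_character_) {
  labs <- paste0("g", sample(seq_len(n)))
  signs <- sample(c("", "-"), n, replace = TRUE)
  gene_order(paste0(signs, labs), taxon = taxon)
}

code5 <- mito_genetic_code("5")
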