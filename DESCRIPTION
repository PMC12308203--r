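Package: coccomito
Title: Descriptive Analytics for AT-Rich Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the descriptive characterization of small circular
    mitochondrial genomes, with defaults tuned to the extremely AT-rich
    mitogenomes of scale insects (Hemiptera, Coccomorpha). Reads genome
    sequences and gene annotations (FASTA, GenBank flat files, tabular
    feature lists), computes nucleotide composition and AT/GC strand skews
    by partition and codon position, gene geometry (lengths, overlaps,
    intergenic spacers, control regions), codon-usage bias metrics (RSCU,
    effective number of codons, codon bias index, GC3), pairwise Ka/Ks by
    Nei-Gojobori counting, heuristic tRNA cloverleaf completeness classes,
    and circular signed gene-order comparisons (breakpoint distances,
    conserved-cluster and apomorphy scans, neighbor-joining trees on
    gene-order distances). A synthetic mitogenome generator with full
    ground-truth bookkeeping supports end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
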