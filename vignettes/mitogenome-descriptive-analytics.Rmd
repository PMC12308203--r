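---
title: "Descriptive analytics for AT-rich mitogenomes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive analytics for AT-rich mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccomito)
```

## Scope and data model

`coccomito` characterizes small circular mitochondrial genomes of the kind
found in scale insects (Hemiptera, Coccomorpha): roughly 16–19 kb, extremely
AT-rich (up to ~91% A+T), with 13 protein-coding genes (PCGs), 22 tRNAs, two
rRNAs, and one or more large non-coding control regions. The package takes an
*annotated* genome — a sequence plus a gene feature table — as its input
contract; de novo annotation (gene finding, covariance-model tRNA detection)
is deliberately out of scope.

Conventions used throughout:

* **Coordinates** are 1-based inclusive. A feature whose `end < start` must
  carry a `wraps_origin` flag and is read through the origin of the circle.
* **Strands** are labelled J (majority) and N (minority), the standard
  insect-mitogenomics vocabulary; `+`/`-` are accepted aliases. N-strand
  features are analyzed on their reverse complement (the sense strand).
* **Genetic code** defaults to NCBI translation table 5 (invertebrate
  mitochondrial): UGA encodes Trp, AGA/AGG encode Ser (an 8-codon family),
  AUA encodes Met, and only UAA/UAG are stops, leaving 62 sense codons. The
  published codon-usage table of the reference genome is only reproducible
  under exactly this family structure, which is why it is the default.
* **Gene names** use a controlled vocabulary (COI…COIII, ATP6/8, ND1–6,
  ND4L, cytb, srRNA/lrRNA, trnX with S1/S2/L1/L2 keyed by anticodon). A
  shipped, editable synonym table maps annotation-engine labels (COX1, nad4l,
  16S, …) onto it.

## Composition and skews

`base_composition()` reports percentages of A/T/G/C with ambiguity codes
excluded from the denominator, plus AT skew $(A-T)/(A+T)$ and GC skew
$(G-C)/(G+C)$. A zero denominator yields `NA`, never 0. Reporting convention:
percentages to 1 decimal, skews to 3 decimals, rounded half away from zero.

Partition semantics matter for reproducing published tables. Codon-position
partitions are computed on each PCG's own coding strand; the "J-strand" /
"N-strand" partitions group genes by the genome strand encoding them but
still count each gene's sense-strand sequence. This is what produces the
characteristic GC-skew sign flip between the J- and N-strand partitions.

One numerical caveat is documented and test-pinned: skews recomputed from
*rounded* percentage tables differ from skews computed on raw counts. Each
1-decimal percentage carries ±0.05; propagated through $(x-y)/(x+y)$ this is
a tolerance of $0.1/(x+y)$ — negligible when the denominator is an A+T
content near 90, but up to ±0.015 for G+C contents as low as 7%. Tests on
printed-percentage inputs therefore assert exactness only where rounding is
self-consistent and use the propagated bound elsewhere.

## Gene geometry

`compute_geometry()` walks the circular feature order, including the wrap
junction from the last feature back to the first, and assigns each junction
a signed spacer `next.start − prev.end − 1`: negative = overlap, zero =
abutting, positive = intergenic spacer. Spacers of at least
`control_region_min` (default 1000 bp) are classified as control regions and
excluded from spacer counts and ranges. The default threshold sits two
orders of magnitude above real spacers (tens of bp) and safely below real
control regions (≥ 2 kb) in these genomes; it is configurable. The wrap
junction's large gap counts as a control region even though classical
structure tables have no row for it; in the tabular report the first
feature's intergenic cell is 0 by convention and the wrap gap appears in the
geometry summary.

The geometry report also checks an exact conservation identity on circular
genomes: gene lengths plus signed junction gaps sum to the genome length.

In the packaged reference annotation, a handful of published table cells
(four tRNA lengths and three intergenic values) are internally inconsistent
with the published coordinates; the coordinates are treated as authoritative,
the printed cells are retained verbatim in the fixture, and the regression
tests pin the documented exceptions explicitly rather than silently
excluding them.

## Codon usage bias

`rscu()` computes relative synonymous codon usage, $n_i k / N$ within each
synonymous family; stop codons form their own 2-codon family and receive
RSCU values (published tables tabulate stop usage), but are excluded from
ENC, CBI, GC and GC3, which are amino-acid based. The 6-codon Leu family is
treated as one family even where published layouts split UUR from CUN — the
printed values are reproducible only under the full-family convention.

`enc()` implements Wright's effective number of codons generalized to an
arbitrary family structure: per-family homozygosity
$\hat F = (n\sum \hat p^2 - 1)/(n-1)$, averaged within family-size classes,
$\mathrm{ENC} = \sum_c N_c/\bar F_c$, capped at the number of sense codons
(62 under table 5; the floor of 20 arises when each amino acid uses a single
codon). Families with $n < 2$ are imputed with their size class's mean; a
wholly missing class is dropped and the total rescaled to the full
sense-codon space. `cbi()` uses the codonW convention
$(N_{opt}-N_{rand})/(N_{tot}-N_{rand})$ with $N_{rand} = \sum_f N_f/k_f$;
the optimal set defaults to each family's most frequent codon in the
analyzed table itself ("all genes" mode) — a declared choice, since no
reference optimal set exists for these taxa. Both metrics are verified
against independent straight-line reimplementations on random tables.

`bias_correlations()` reports Spearman correlations by default (the
empirical relationships along AT-content gradients are monotone, and no
method is standard in this literature; Pearson is available by argument).
Only the *signs* of these correlations are treated as reproducible claims,
and the simulated AT-gradient panel (`simulate_codon_panel()`) recovers the
expected `(+, +, −, −, −)` pattern for ENC~GC, ENC~GC3, CBI~GC, CBI~GC3,
ENC~CBI.

## Selection (Ka/Ks)

`ng86_kaks()` implements Nei–Gojobori (1986) counting: fractional
synonymous/nonsynonymous site counts per codon (stop neighbors excluded
from the position's denominator; sites averaged over the two sequences),
equal-weight averaging of minimal substitution pathways for multi-difference
codons with stop-traversing pathways excluded, and the Jukes–Cantor
correction $d = -\tfrac34\ln(1-\tfrac43 p)$. Proportions at or beyond the
correction's domain ($p \ge 3/4$) return a saturation marker rather than a
number — note that this is mathematically forced even for a single
synonymous difference observed in a lone codon, where $p_s$ exceeds 1.

This module is an explicit methodological substitution: maximum-likelihood
codon models that correct for AT-content-induced mutation bias (FMutSel-type
models) are out of scope, and NG86 is known to be biased downward at high
divergence and under strong compositional bias. Accordingly the package
makes no numeric claims about real per-gene Ka/Ks values; its acceptance
surface is property-based: exhaustive path-enumeration equivalence on short
pairs, symmetry, site conservation, rank recovery of $\omega$ across
simulated values {0.1, 0.5, 1.0} (500 codons, 20 replicates, fixed seeds),
and ≥95% of defined ratios below 1 under a purifying ($\omega = 0.1$)
simulation. The simulated branch length (t = 0.3 expected attempted neutral
substitutions per site) was chosen once as a moderate-divergence regime well
inside the correction's domain.

## tRNA cloverleaf classes

Mitochondrial tRNAs in these lineages routinely lack the D arm, the T arm,
or both. `detect_arms()` is a transparent heuristic anchored on the
annotated anticodon: a 7-nt anticodon loop centered on the triplet, an
anticodon stem of contiguous complementary pairs flanking it, an acceptor
stem between the molecule's ends (allowing up to 4 nt of unpaired 3'
overhang), and D-/T-arm hairpins (stem ≥ 3 pairs, loop 3–11 nt, G·U counted
as a pair) searched in the windows 5' and 3' of the anticodon arm. The
completeness class is `full`, `D-armless`, `T-armless` or `minimal`.
Thresholds (`min_stem_pairs = 3`, `min_acceptor_pairs = 4`) reproduce
canonical cloverleafs on constructed fixtures and are configurable. The
classifier must, and does, tolerate genes as short as ~40 nt. Because the
reference genome's sequence is not published, real-sequence agreement cannot
be tested; acceptance is fixture- and simulator-based, which demonstrates
the classifier's behavior on clean and deliberately degraded structures,
not its accuracy on real annotation-engine output.

## Circular gene orders

Gene orders are signed circular permutations (sign = strand).
`canonicalize()` rotates to a fixed anchor (COI, positive; the whole order
is reflected first if the anchor is negative), making
rotation/reflection-equivalent orders compare equal.
`breakpoint_distance()` counts signed adjacencies ($x \to y$ identified
with $-y \to -x$) present in one order but not the other — a pseudometric
sufficient for the descriptive rearrangement claims; inversion distance
(Hannenhalli–Pevzner) is deliberately not implemented. `find_cluster()`
matches signed patterns circularly, also reporting inverted occurrences;
`apomorphy_scan()` flags patterns confined to a single taxon group
(`fixed` when present in every member) — the rearrangement analogue of a
derived character state. `nj_tree()` is plumbing: standard neighbor joining
(via ape) on the breakpoint-distance matrix with negative branches clamped
to zero.

The packaged multi-taxon order set is a *schematic, synthetic* fixture: the
ancestral insect arrangement plus, per taxon, only the documented
ND2-neighborhood clusters and named gene blocks, with all other genes left
ancestral. Cluster presence/absence on it is faithful; pairwise distances
between schematic orders are illustrative only and are never asserted.

## The synthetic genome generator

`simulate_mitogenome()` exists so that every pipeline stage can be tested
closed-loop against known ground truth. Its defaults are the study
conditions: an 18,830 bp circular genome at 90.7% A+T, the reference
37-gene order with published PCG/rRNA lengths, 15 overlaps, 14 spacers
(1–72 bp), two control regions, and tRNA classes split 8 full / 8 T-armless
/ 5 D-armless / 1 minimal. PCGs are sampled codon-by-codon from the
published codon-frequency table (ATN start, TAA stop, internal stops
excluded by construction); tRNAs are written from the structural templates;
remaining positions are i.i.d. with the A/T rate solved so the whole-genome
A+T matches the target in expectation (realized values land within a few
tenths of a percentage point; the contract, and the test, is ±1%).

Overlap realization required a design decision. Overlapping genes share
genome positions, so one neighbor's written content must win. The generator
uses the ownership priority PCG > tRNA > rRNA > background and shapes the
default junction profile so ownership never corrupts a recovered quantity:
protein–protein junctions carry no overlap (codon content and TAA stops
stay exact), and overlaps where a tRNA is the non-owning party are capped
at 7 bp, so only acceptor-stem flanks — which do not enter the D-/T-arm
windows that define the completeness class — are overwritten. Replaced arms
are adenine runs, which cannot base-pair internally, so an absent arm cannot
be rediscovered by the hairpin search. The overlap count and ranges still
match the study profile; individual overlap lengths at capped junctions do
not, which is the one respect in which the default geometry is idealized
rather than transcribed.

Each sub-generator draws from its own seed-derived stream, so adding a
generator never shifts another's draws and runs are byte-reproducible.
`evolve_codon_pair()` provides the Ka/Ks harness (single-nucleotide codon
model; transitions scaled by κ, nonsynonymous changes by ω, stops
unreachable), and `perturb_gene_order()` applies logged
transposition/inversion events for rearrangement tests.

What passing the closed loop does *not* show: the simulator writes clean,
template-structured tRNAs and exact annotations, so recovery there says
nothing about robustness to mis-annotated boundaries, sequencing error, or
real secondary-structure diversity. Those limits are inherent to testing
against synthetic ground truth.

## Problem sizes and reproducibility

The default test suite simulates full-size (18.8 kb) genomes, uses
500-codon alignments with 20 replicates per ω level for the selection
properties, 200 random order pairs for the pseudometric checks, and
8 × 8000-codon panels for the bias-correlation signs; the whole suite runs
in well under a minute. All randomized tests fix seeds. The
`scripts/acceptance.R` entry point recomputes the headline reference
quantities (RSCU spot values, geometry counts, partition skews) from the
packaged tables alone and writes them as JSON.
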