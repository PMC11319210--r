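---
title: "Methods: pangenome composition, centromere localization and SV landscapes"
author: "panmelon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome composition, centromere localization and SV landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmelon)
```

# Scope

`panmelon` implements the analytical core of a genus-level plant
super-pangenome study of the kind built from telomere-to-telomere (T2T)
watermelon assemblies: gene-family presence–absence (PAV) analysis,
centromere and telomere localization from assembled chromosomes, and
structural-variant (SV) landscape characterization including two-ancestor
inheritance partitioning. Assembly, annotation and alignment-based SV
calling are upstream of this package: its inputs are a PAV matrix, FASTA
assemblies, GFF3 gene models, repeat BED files and per-accession SV call
sets. A synthetic-genome generator with ground-truth manifests makes every
stage testable without external data.

All intervals are 0-based half-open internally. GFF3 (1-based closed) and
VCF `POS` (1-based) are converted at the reader boundary, which keeps every
piece of interval arithmetic in one convention.

# PAV pangenome model

For $N$ accessions, a gene family present in $k$ accessions is

* **core** if $k = N$;
* **softcore** if it is absent in exactly 1 or 2 accessions
  ($k \in \{N-1, N-2\}$);
* **private** if $k = 1$;
* **dispensable** otherwise.

Precedence is core > softcore > private > dispensable. The precedence
matters only on small panels, but conceptually a family found in a single
accession satisfies both "missing in more than two" and "exclusive to one";
exclusivity wins so that the four-way partition with a private class is
produced. At species level a family is "present in a species" when at least
one member accession carries it, and only three classes exist (core,
dispensable, private) — with about seven species there is no meaningful
species-level softcore.

## Saturation and closure

Pan- and core-genome saturation curves use random orderings of the
accessions (sampling without replacement; 100 replicates by default,
matching common practice). At each prefix length $n$, the pan size counts
families present in at least one of the first $n$ accessions, the core size
those present in all of them. Per replicate, pan sizes are non-decreasing
and core sizes non-increasing — asserted as an invariant in the tests.

Closure is decided by a Heaps-law decay fit. With
$\Delta(n) = \overline{\mathrm{pan}(n) - \mathrm{pan}(n-1)}$ the mean
number of new families contributed by the $n$-th genome, the model

$$\Delta(n) = \kappa\, n^{-\alpha}$$

is fitted by least squares on $\log \Delta(n)$ over $n = 2..N$ (zero means
are dropped; fewer than three usable points is an error). The pangenome is
**closed** when $\alpha > 1$: the series $\sum_n \kappa n^{-\alpha}$ then
converges, so adding further genomes contributes asymptotically no new
families. A panel of identical accessions has $\Delta \equiv 0$ and is
reported closed with an $\alpha = \infty$ sentinel. The threshold and the
model form follow the standard Heaps-law treatment of pangenome openness.

## Diversity and distance

Per-family nucleotide diversity over an alignment of $n$ sequences is

$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L_{ij}},$$

where $d_{ij}$ counts mismatching positions and positions carrying a gap or
`N` in either sequence are excluded from both $d_{ij}$ and the pair's
effective length $L_{ij}$. A pair with $L_{ij} = 0$ makes $\pi$ undefined
(`NA` with a warning).

The accession distance for PAV trees is the Jaccard distance
$d(A,B) = 1 - |A \cap B| / |A \cup B|$ on family presence sets — a natural
metric for binary presence data; no canonical metric exists for PAV trees,
so this is a package design choice.

# Neighbor joining and monomer comparison

Trees are built with classical Saitou–Nei neighbor joining: join the pair
minimizing $Q(i,j) = (m-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with
ties broken deterministically by the lexicographic order of the smallest
leaf label under each node. Negative branch-length estimates are clamped to
zero and flagged. On additive matrices the output reproduces the input path
lengths exactly, which the tests verify against the four-point condition
and against `ape::nj` as an independent cross-check.

Monomer comparison uses the normalized edit distance
$\mathrm{lev}(a,b)/\max(|a|,|b|)$. This replaces the aligner + maximum
likelihood route (MAFFT + FastTree) that a full-scale study would use — an
explicit simplification: at desk scale the quantity that matters is
cluster separation of monomer families, which edit distance preserves,
and it removes the dependency on external binaries. Maximum-likelihood
inference and bootstrap support are out of scope.

# Tandem repeats, centromeres, telomeres

## Detection

`find_tandem_repeats()` replaces a probabilistic-alignment repeat finder
with a transparent two-stage procedure:

1. **Seeding** — candidate periods are the distances between re-occurrences
   of identical $k$-mers ($k$ adapts between 4 and 12 to `min_period`).
2. **Verification and extension** — a candidate period $p$ at position $s$
   is accepted when a window aligned against itself shifted by $p$ reaches
   `min_identity` matching bases; arrays are then extended monomer-by-
   monomer left and right while the per-monomer identity holds.

Periods that are multiples of a smaller valid period are collapsed to the
smallest divisor that still verifies, so a dimer of the true monomer is
never reported. Overlapping arrays are merged keeping the higher-scoring
(copy number × identity) one. Defaults: `min_period = 5`,
`max_period = 500`, `min_copies = 5`, `min_identity = 0.8`. The tests
compare detected periods against a brute-force shifted-self-identity scan
over every period 5..200 and require span recovery within one monomer.

With 5% per-copy divergence, adjacent copies still match at ≈ 90% identity
(two independent 5% mutation processes), comfortably above the 0.8
threshold; the threshold would need lowering only for satellite families
beyond ~10% divergence.

## Monomer clustering

Greedy incremental clustering in the style of CD-HIT: monomers are
processed by decreasing length and join the first cluster whose
representative identity ($1 -$ normalized edit distance, both strands
tried) reaches the threshold (default 0.8), otherwise they found a new
cluster. Cluster **abundance** is the summed copy number of member arrays —
centromere pipelines rank "top" monomer clusters without a standard
definition of abundance, and
copy count (rather than member count) is the choice here because it weighs
a 3,000-copy satellite above three stray 5-copy arrays. Ranks order by
abundance; `top_clusters(, 8)` keeps the conventional top eight.

## Centromere calling

Windows (default 100 kb, step 50 kb) tiling a chromosome are scored as

$$w_1 \cdot \text{monomer coverage} + w_2 \cdot \text{Gypsy bp fraction}
  - w_3 \cdot \text{gene count} / \max(\text{gene count})$$

with default weights $(1.0, 0.3, 0.3)$: tandem-array coverage by the top
monomer clusters is the primary signal, Gypsy LTR density (elevated in
plant centromeres) is corroborating, and gene density is a penalty.
Candidate regions are maximal runs of consecutive windows with monomer
coverage ≥ 0.3; the run with the highest mean score is the single call
(monocentric assumption; ties to the leftmost). "Continuous and
high-frequency" is a qualitative notion; the 0.3 coverage
threshold over consecutive windows is this package's operationalization,
exposed as `c_min`.

Because the call is a union of windows, its boundary resolution is one
window; at the default geometry (500 kb centromere, 100 kb windows) the
recovered span carries about 50 kb of slack per side, i.e. a Jaccard of
roughly 0.83–0.91 against truth — the recovery tests require ≥ 0.8.

## Telomeres

The plant telomere motif `CCCTAAA` is counted in the 5′ terminal window and
its reverse complement `TTTAGGG` in the 3′ window (default 10 kb); an end is
telomere-positive at ≥ 10 copies. A complete T2T genome of 11 chromosomes
therefore reports 22 telomere-positive ends. Reverse-complementing a
chromosome swaps the two calls, asserted as a strand-consistency invariant.

# SV landscape

SVs shorter than 21 bp are excluded at the reader (the > 20 bp floor of the
five-category landscape). Merging into a nonredundant set takes connected
components of a pairwise criterion with community-standard
(SURVIVOR/truvari-like) defaults, there being no single universal
convention for building nonredundant sets:

* DEL/DUP/INV: reciprocal overlap ≥ 0.5 (both directions);
* INS: anchor points within 100 bp and length ratio ≥ 0.5;
* TRA: both breakpoints within 100 bp.

The representative is the member with the (lower) median length; presence
vectors union the member accessions. Because representatives are original
members, re-merging the output is the identity (idempotence, tested), and
the result is invariant to input order.

Annotation context uses precedence cds > genic_noncds > flank2kb >
intergenic by any-overlap of the SV span (insertions: anchor point) with
CDS parts, gene spans, and gene spans ± 2 kb. The coding effect for
CDS-overlapping DEL/INS/DUP is sequence-free — frameshift iff length mod 3
≠ 0, else in-frame; CDS-overlapping INV/TRA are "structural". Repeat
enrichment compares SV midpoints (midpoint membership avoids double
counting across bins) against the genomic repeat/nonrepeat bp composition
in a 2×2 two-sided Fisher's exact test (p = sum over tables with the
observed margins whose probability does not exceed the observed one; the
implementation is `stats::fisher.test`, checked against exhaustive
hypergeometric enumeration in the tests). Inversion hotspots are merged
1 Mb windows (100 kb slide) holding ≥ 3 inversion midpoints.

"Core SVs" of a target group are nonredundant records present in every
accession of the group — the strictest reading of "core", chosen because
looser definitions (majority presence) blur the inheritance signal. The
ancestor partition then classifies
each core SV by presence in the two candidate ancestor accessions:
inherited from A only, B only, both, or neither.

Type percentages are rounded half away from zero to two decimals for
report parity with published category tables (base `round()` would apply
banker's rounding).

# Synthetic data: what it emulates and what it does not

The generators define the package's study conditions; their defaults were
fixed once, at design time:

* `simulate_pav()` — 28 accessions in 7 species groups (14/2/5/4/1/1/1,
  mirroring a genus-wide watermelon panel), 20,000 families, class
  proportions 42.78/8.80/45.87/2.55% (published per-genome class
  percentages, which sum to exactly 100). Class constructions are exactly
  separable: dispensable occupancy $k$ is drawn from a truncated geometric
  on $[2, N-3]$ (decay 0.3), so a dispensable family can never satisfy the
  softcore or private definitions. The truncated geometric gives the
  low-occupancy arm of the U-shaped occupancy spectrum typical of real
  pangenomes; the high arm comes from the core/softcore mass. No published
  occupancy spectrum exists to calibrate against, so the decay rate is a
  design choice.
* `simulate_chromosome()` — 2 Mb chromosomes with a 500 kb centromere
  (roughly a 15× shrink of a ~30 Mb watermelon chromosome that keeps the
  centromere proportion), a random 100 bp monomer mutated at 5% per base
  per copy (substitutions only), Gypsy elements at 10/Mb on the arms and
  5× that inside the centromere, 65 genes/Mb on the arms, and 100 copies of
  `CCCTAAA` / `TTTAGGG` at the ends.
* `simulate_sv_landscape()` — five SV types at the published category
  fractions (46.99/51.88/0.67/0.28/0.18%), per-type log-normal lengths
  offset past the 20 bp floor (published length distributions are only
  shown graphically, so the log-normal parameters are stated defaults, not
  calibrated), midpoint placement with repeat-membership odds multiplied by
  the enrichment factor, and a two-ancestor design in which every SV is
  carried by the whole target group and by ancestors according to its
  origin (default origin proportions 33/68/200/61 over 362, the published
  Venn partition).

Deliberately **not** emulated: real TE landscapes and nested repeats,
insertion/deletion divergence inside satellite monomers (substitutions
only), assembly errors and gaps, SV breakpoint jitter between accessions
(coordinates are shared exactly, so merging stress comes from the random
fixtures in the tests rather than the generator), orthology-inference
noise in the PAV matrix, and read-level data. Passing recovery tests
therefore demonstrate correctness of the analysis logic under the stated
models — not robustness to every artifact of real assemblies.

All generators are deterministic per seed (single integer-seeded RNG
stream, no iteration-order dependence), and every generator's output
passes the corresponding reader's validation.

# Numerical and statistical choices

* Degenerate inputs: empty PAV matrices, < 4 accessions, < 3 species,
  sequences shorter than twice the telomere window, and zero-marginal
  enrichment tables are rejected or flagged rather than coerced.
* NJ tie-breaks are lexicographic; centromere-run ties go to the leftmost;
  merge representatives take the lower median; all outputs are
  reproducible bit-for-bit under a fixed seed.
* Closure fitting drops $\Delta(n) = 0$ points (log-undefined) and errors
  below three usable points.
* Proportion-recovery tests compare observed class fractions against
  generator parameters within binomial confidence intervals that are
  Bonferroni-adjusted across the simultaneous per-class comparisons, so
  each recovery check operates at a joint 95% level; per-class 95%
  intervals applied independently to nine categories would fail roughly a
  third of correct implementations by construction.
* Problem sizes in the tests and acceptance script (20,000 families × 28
  accessions × 100 replicates; 20 × 2 Mb chromosomes; 2,000-SV landscapes;
  200 null simulations at 1,000 SVs) are the package's desk-scale defaults:
  large enough for the binomial bands to be informative, small enough to
  run on a laptop.

# Known limitations

* Tandem-repeat detection assumes substitution-dominated divergence;
  indel-rich satellite families can fragment an array into several calls
  (the centromere caller reassembles them through window coverage, but the
  reported per-array copy numbers then undercount).
* Centromere boundaries are window-quantized; sub-window precision would
  need a refinement pass over array coordinates.
* The species-level classifier treats a species as present on a single
  member hit, which is permissive for noisy PAV matrices.
* The enrichment test conditions on the genomic bp composition as a fixed
  margin; at very small SV counts its discreteness makes it conservative.
* `merge_svs()` is quadratic within dense breakpoint clusters; it is
  intended for desk-scale sets (up to ~10^5 records), not population-scale
  call sets.
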