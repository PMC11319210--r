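# panmelon

Pangenome composition, centromere/telomere localization and
structural-variant (SV) landscape analysis for genus-level plant
super-pangenomes — the analytical layer of studies that assemble
telomere-to-telomere (T2T) genomes for a crop and its wild relatives
(the motivating case is watermelon, *Citrullus*, with 28 accessions across
seven species) and ask: how much of the gene repertoire is shared, is the
pangenome closed, where are the centromeres, and which structural variants
did the crop inherit from which ancestor?

It is written for researchers who have the upstream products of such a
study — a gene-family presence–absence (PAV) matrix, assemblies (FASTA),
gene models (GFF3), repeat annotations (BED) and per-accession SV call
sets (VCF or TSV) — and want the downstream analyses reproducible and
testable. A synthetic-genome generator with ground-truth manifests lets
every stage be validated by parameter recovery without any external data.

## What it computes

**PAV pangenome.** Families present in $k$ of $N$ accessions are core
($k=N$), softcore (absent in 1–2), private ($k=1$) or dispensable
(precedence core > softcore > private > dispensable). Saturation curves
over random accession orderings (100 replicates) feed a Heaps-law closure
fit $\Delta(n) = \kappa n^{-\alpha}$: the pangenome is closed iff
$\alpha > 1$. Per-family nucleotide diversity
$\pi = \tfrac{2}{n(n-1)}\sum_{i<j} d_{ij}/L_{ij}$ and Jaccard PAV
distances (with neighbor-joining trees) complete the module.

**Centromeres and telomeres.** Tandem arrays are detected by k-mer-seeded
period estimation with shifted-self-identity verification, monomers are
clustered greedily at 80% identity (CD-HIT style), and one centromere per
chromosome is called from windowed evidence — monomer coverage of the top
clusters, Gypsy LTR density, and a gene-density penalty. Telomere
completeness counts `(CCCTAAA)n` / `(TTTAGGG)n` at chromosome ends.

**SV landscape.** Per-accession call sets (> 20 bp; DEL/INS/DUP/INV/TRA)
are merged into a nonredundant set by connected components of a
reciprocal-overlap criterion, summarized by type, annotated by genomic
context (CDS / genic / 2 kb flank / intergenic, repeat membership,
frameshift vs in-frame coding effects), tested for repeat-region
enrichment with a two-sided Fisher's exact test, scanned for inversion
hotspots, and — for a target group's core SVs — partitioned by inheritance
from two candidate ancestor accessions.

## Worked example

The `analysis/` directory is a four-step workflow over simulated inputs
(`01_simulate_data.R` → `04_sv_landscape.R`). Running steps 1–2:

```
$ Rscript analysis/01_simulate_data.R
Simulated: 20000 families x 28 accessions; 3 chromosomes (6.0 Mb);
10756 SV records over 6 accessions (true nonredundant SVs: 2000).

$ Rscript analysis/02_pangenome_composition.R
Pangenome classification (accession level):
       class count fraction    pct
        core  8496  0.42480 42.48%
    softcore  1792  0.08960  8.96%
 dispensable  9307  0.46535 46.53%
     private   405  0.02025  2.02%
Heaps-law closure fit: alpha = 1.579 (closed pangenome)
```

The recovered class percentages match the generator's proportions (the
published per-genome averages 42.78/8.80/45.87/2.55%) to within sampling
error, and the decay exponent α = 1.58 > 1 declares the simulated panel a
closed pangenome. Step 4 prints the SV landscape, e.g.:

```
Merged 10756 records into 1985 nonredundant SVs.
 type count percent
  DEL   931   46.90
  INS  1030   51.89
Repeat enrichment: 299.1 vs 100.8 SVs per 500 kb (repeat vs nonrepeat),
OR = 2.97, p = 1.15e-127
Core SVs of the target group: 1985; inherited from ancestor A only: 199,
from ancestor B only: 385, from both: 1080, from neither: 321.
```

— i.e. the 3× simulated repeat enrichment and the 33:68:200:61-shaped
origin proportions are recovered by the merge → partition pipeline.

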