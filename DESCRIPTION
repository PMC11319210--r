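Package: panmelon
Title: Pangenome Composition, Centromere Localization and Structural-Variant
    Landscape Analysis for Plant Super-Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genus-level plant super-pangenome analysis of the kind
    used for telomere-to-telomere watermelon (Citrullus) assemblies:
    presence-absence (PAV) classification of gene families into core, softcore,
    dispensable and private classes; pangenome/core-genome saturation curves and
    Heaps-law closure fitting; per-family nucleotide diversity; tandem-repeat
    detection, monomer clustering and weighted-evidence centromere calling;
    CCCTAAA telomere completeness scans; cross-accession structural-variant
    merging, genomic-context annotation, repeat-region enrichment testing,
    inversion hotspots and two-ancestor inheritance partitioning; and
    neighbor-joining trees from PAV or monomer distances. A synthetic-genome
    generator with ground-truth manifests makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
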