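# SV merging, summaries, annotation, enrichment, hotspots, ancestry and the
# Bonferroni helper.

one_sv <- function(acc, chrom, start, end, type, length = end - start) {
  data.frame(accession = acc, chromosome = chrom, start = start, end = end,
             type = type, length = length, stringsAsFactors = FALSE)
}

test_that("merging follows the pairwise criterion via connected components", {
  # one accession: identity, singleton presence vectors
  recs <- random_sv_records(40, seed = 1, accessions = "solo")
  nr <- merge_svs(recs)
  expect_equal(sum(nr$table$n_members), nrow(recs))
  expect_true(all(rowSums(nr$presence) >= 1))

  # identical DELs in two accessions collapse to one record present in both
  two <- rbind(one_sv("a1", "chr1", 100, 400, "DEL"),
               one_sv("a2", "chr1", 100, 400, "DEL"))
  nr2 <- merge_svs(two)
  expect_equal(nrow(nr2$table), 1L)
  expect_true(all(nr2$presence[1, c("a1", "a2")]))

  # 40% reciprocal overlap at threshold 0.5 stays split
  forty <- rbind(one_sv("a1", "chr1", 0, 1000, "DEL"),
                 one_sv("a2", "chr1", 600, 1600, "DEL"))
  expect_equal(nrow(merge_svs(forty)$table), 2L)
  expect_equal(nrow(merge_svs(forty, reciprocal_overlap = 0.4)$table), 1L)

  # 200-record fixture against the transitive-closure oracle
  recs200 <- random_sv_records(200, seed = 2, span_max = 2e4)
  expect_same_partition(merge_svs(recs200), recs200)
})

test_that("merging is idempotent and input-order invariant", {
  recs <- random_sv_records(120, seed = 3, span_max = 1.5e4)
  nr <- merge_svs(recs)
  # re-merge the representatives, one record per carried accession
  again <- do.call(rbind, lapply(seq_len(nrow(nr$table)), function(i) {
    carriers <- colnames(nr$presence)[nr$presence[i, ]]
    df <- nr$table[rep(i, length(carriers)), c("chromosome", "start", "end",
                                               "type", "length")]
    df$accession <- carriers
    df
  }))
  nr2 <- merge_svs(again)
  cols <- c("chromosome", "start", "end", "type", "length")
  expect_equal(nr2$table[, cols], nr$table[, cols], ignore_attr = TRUE)
  expect_equal(unname(nr2$presence), unname(nr$presence))

  shuffled <- recs[sample.int(nrow(recs)), ]
  nr3 <- merge_svs(shuffled)
  expect_equal(nr3$table$start, nr$table$start)
  expect_equal(nr3$table$n_members, nr$table$n_members)
})

test_that("type summaries reproduce printed-count arithmetic", {
  counts <- c(DEL = 217076, INS = 239698, DUP = 3122, INV = 1278, TRA = 813)
  sm <- summarize_types(counts)
  expect_equal(attr(sm, "total"), 461987)
  expect_equal(sm$percent[sm$type == "DEL"], 46.99)
  expect_equal(sm$percent[sm$type == "INS"], 51.88)
  expect_equal(sm$percent[sm$type == "INV"], 0.28)

  single <- summarize_types("DEL")
  expect_equal(single$percent[single$type == "DEL"], 100)

  set.seed(9)
  codes <- sample(c("DEL", "INS", "DUP", "INV", "TRA"), 500, replace = TRUE)
  sm2 <- summarize_types(codes)
  tally <- table(factor(codes, c("DEL", "INS", "DUP", "INV", "TRA")))
  expect_equal(sm2$count, as.numeric(tally))
  expect_equal(sm2$percent, round(100 * as.numeric(tally) / 500 + 1e-12, 2))
})

test_that("annotation respects context precedence and coding-effect rules", {
  genes <- list(list(id = "g1", chromosome = "chr1", start = 10000,
                     end = 15000, strand = "+",
                     cds_parts = cbind(start = 11000, end = 12000)))
  repeats <- data.frame(chromosome = "chr1", start = 40000, end = 45000,
                        class = "LTR/Gypsy")
  recs <- rbind(
    one_sv("a1", "chr1", 11500, 11505, "DEL"),  # inside CDS, 5 bp
    one_sv("a1", "chr1", 8500, 8500, "INS", 50),  # 1.5 kb upstream anchor
    one_sv("a1", "chr1", 30000, 30100, "DEL"),  # > 2 kb from genes
    one_sv("a1", "chr1", 41000, 41120, "INV"),  # in repeat; no gene
    one_sv("a1", "chr1", 13000, 13200, "DUP"))  # genic, outside CDS
  nr <- merge_svs(recs)
  ann <- annotate_svs(nr, genes, repeats)
  # annotations come back in table order, i.e. sorted by start
  a <- ann$annotations
  expect_equal(a$context,
               c("flank2kb", "cds", "genic_noncds", "intergenic",
                 "intergenic"))
  expect_equal(a$coding_effect[a$context == "cds"], "frameshift")
  expect_equal(a$coding_effect[a$context == "genic_noncds"], "none")
  expect_true(a$in_repeat[5])
  expect_false(a$in_repeat[4])
  # context fractions partition the annotated set
  expect_equal(sum(ann$summary[c("cds", "genic_noncds", "flank2kb",
                                 "intergenic")]), 1, tolerance = 1e-9)

  # in-frame deletion
  inframe <- merge_svs(one_sv("a1", "chr1", 11500, 11530, "DEL"))
  expect_equal(annotate_svs(inframe, genes, repeats)$annotations$coding_effect,
               "inframe")
  # inversions across CDS are structural
  strc <- merge_svs(one_sv("a1", "chr1", 10500, 12500, "INV"))
  expect_equal(annotate_svs(strc, genes, repeats)$annotations$coding_effect,
               "structural")
  # unknown chromosomes are flagged and excluded
  mixed <- merge_svs(rbind(one_sv("a1", "chr1", 11500, 11505, "DEL"),
                           one_sv("a1", "chrZ", 100, 200, "DEL")))
  annx <- annotate_svs(mixed, genes, repeats)
  expect_equal(length(annx$excluded), 1L)
  expect_equal(nrow(annx$annotations), 1L)
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  # symmetric table: no association
  expect_equal(stats::fisher.test(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
  m <- matrix(c(12, 3, 5, 10), 2, byrow = TRUE)
  expect_equal(stats::fisher.test(m)$p.value, fisher_enum(m),
               tolerance = 1e-10)
  # random small tables with margins <= 30
  set.seed(6)
  for (i in 1:40) {
    m <- matrix(rpois(4, 5), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(stats::fisher.test(m)$p.value, fisher_enum(m),
                 tolerance = 1e-9)
  }
})

test_that("repeat enrichment wires midpoints and bp composition correctly", {
  repeats <- data.frame(chromosome = "chr1", start = 0, end = 5e4,
                        class = "LTR/Gypsy")
  lens <- c(chr1 = 1e5)
  inside <- do.call(rbind, lapply(1:12, function(i)
    one_sv("a1", "chr1", 1000 * i, 1000 * i + 100, "DEL")))
  outside <- do.call(rbind, lapply(1:3, function(i)
    one_sv("a1", "chr1", 6e4 + 2000 * i, 6e4 + 2000 * i + 100, "DEL")))
  nr <- merge_svs(rbind(inside, outside))
  en <- repeat_enrichment(nr, repeats, lens)
  expect_equal(unname(en$table[1, ]), c(12, 3))
  expect_equal(unname(en$table[2, ]), c(5e4, 5e4))
  expect_equal(en$odds_ratio, 4)
  expect_equal(en$p_value, stats::fisher.test(en$table)$p.value)
  expect_equal(en$density_repeat / en$density_nonrepeat, 4)
})

test_that("ancestry partition performs the set algebra of the Venn diagram", {
  # realize the published-style partition: 33 A-only, 68 B-only, 200 shared,
  # 61 in neither ancestor; the complement must come out as 61
  build <- function(nA, nB, nBoth, nNone) {
    total <- nA + nB + nBoth + nNone
    origin <- rep(c("onlyA", "onlyB", "both", "neither"),
                  c(nA, nB, nBoth, nNone))
    recs <- do.call(rbind, lapply(seq_len(total), function(i) {
      carriers <- c("t1", "t2",
                    if (origin[i] %in% c("onlyA", "both")) "ancA",
                    if (origin[i] %in% c("onlyB", "both")) "ancB")
      do.call(rbind, lapply(carriers, function(a)
        one_sv(a, "chr1", i * 1e4, i * 1e4 + 500, "DEL")))
    }))
    # each ancestor also carries a private SV far away (non-core noise)
    recs <- rbind(recs,
                  one_sv("ancA", "chr1", 9e6, 9e6 + 500, "DEL"),
                  one_sv("ancB", "chr1", 9.5e6, 9.5e6 + 500, "DEL"))
    merge_svs(recs)
  }
  nr <- build(33, 68, 200, 61)
  ap <- ancestry_partition(nr, c("t1", "t2"), "ancA", "ancB")
  expect_equal(ap$total, 362)
  expect_equal(unname(ap$counts), c(33, 68, 200, 61))
  expect_equal(ap$total - sum(ap$counts[c("onlyA", "onlyB", "both")]), 61)

  # disjoint ancestors: everything lands in neither
  nr2 <- build(0, 0, 0, 10)
  ap2 <- ancestry_partition(nr2, c("t1", "t2"), "ancA", "ancB")
  expect_equal(unname(ap2$counts), c(0, 0, 0, 10))

  # random memberships against direct set algebra on the presence matrix
  set.seed(10)
  recs <- random_sv_records(150, seed = 44, span_max = 1e6,
                            accessions = c("t1", "ancA", "ancB"))
  recs <- rbind(recs, transform(recs[recs$accession == "ancA", ][1:5, ],
                                accession = "t1"))
  nr3 <- merge_svs(recs)
  ap3 <- ancestry_partition(nr3, "t1", "ancA", "ancB")
  pm <- nr3$presence
  core <- pm[, "t1"]
  expect_equal(unname(ap3$counts["onlyA"]),
               sum(core & pm[, "ancA"] & !pm[, "ancB"]))
  expect_equal(unname(ap3$counts["neither"]),
               sum(core & !pm[, "ancA"] & !pm[, "ancB"]))
  expect_equal(sum(ap3$counts), ap3$total)
})

test_that("inversion hotspots are sliding-window maximal runs", {
  # 5 inversions inside one 1-Mb window
  recs <- do.call(rbind, lapply(1:5, function(i)
    one_sv("a1", "chr1", 1e5 * i, 1e5 * i + 5000, "INV")))
  nr <- merge_svs(recs)
  hs <- inversion_hotspots(nr, min_count = 3)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_inversions, 5)
  mids <- (recs$start + recs$end) %/% 2
  expect_true(all(mids >= hs$start & mids < hs$end))

  # no inversions -> empty
  expect_equal(nrow(inversion_hotspots(merge_svs(
    one_sv("a1", "chr1", 10, 600, "DEL")))), 0L)

  # inversions 2 Mb apart never share a window at min_count 2
  far <- rbind(one_sv("a1", "chr1", 1e6, 1e6 + 5000, "INV"),
               one_sv("a1", "chr1", 3e6, 3e6 + 5000, "INV"))
  expect_equal(nrow(inversion_hotspots(merge_svs(far), min_count = 2)), 0L)
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_lt(abs(bonferroni_threshold(0.05, 9618384) - 5.19e-9) / 5.19e-9,
            0.01)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})
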