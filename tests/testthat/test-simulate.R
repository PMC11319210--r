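# Synthetic generators: determinism, class constructions, parameter errors,
# and compatibility of generator output with the readers' validation.

test_that("PAV generator is deterministic and classes are recoverable", {
  s1 <- simulate_pav(seed = 5, n_families = 2000)
  s2 <- simulate_pav(seed = 5, n_families = 2000)
  expect_identical(s1, s2)

  # all-core proportions: every accession column identical
  allcore <- simulate_pav(n_accessions = 6, n_families = 50,
                          species_map = stats::setNames(rep(c("x", "y", "z"),
                                                            2),
                                                        paste0("a", 1:6)),
                          class_proportions = c(1, 0, 0, 0), seed = 2)
  expect_true(all(allcore$pav$presence))

  # classifier recovers the manifest classes (exact by construction)
  sim <- simulate_pav(seed = 8, n_families = 5000)
  cl <- classify_families(sim$pav)
  expect_gte(mean(cl$label_of == sim$manifest$true_family_classes), 0.99)

  expect_error(simulate_pav(n_accessions = 3,
                            species_map = stats::setNames(c("x", "y", "z"),
                                                          paste0("a", 1:3))),
               ">= 4")
  expect_error(simulate_pav(class_proportions = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("chromosome generator builds the advertised structure", {
  ch <- simulate_chromosome(length = 4e5, centromere_span = c(15e4, 25e4),
                            monomer_divergence = 0, telomere_copies = 20,
                            seed = 4)
  expect_identical(ch,
                   simulate_chromosome(length = 4e5,
                                       centromere_span = c(15e4, 25e4),
                                       monomer_divergence = 0,
                                       telomere_copies = 20, seed = 4))
  expect_equal(nchar(ch$sequence), 4e5)
  # zero divergence: centromere is an exact tandem of the manifest monomer
  cen <- substr(ch$sequence, 15e4 + 1, 25e4)
  expect_equal(cen, substr(strrep(ch$manifest$true_monomer, 1001), 1, 1e5))
  # telomeric caps on both ends
  expect_equal(substr(ch$sequence, 1, 14), strrep("CCCTAAA", 2))
  expect_equal(substr(ch$sequence, 4e5 - 13, 4e5), strrep("TTTAGGG", 2))
  # annotations stay inside the chromosome and genes avoid the centromere
  expect_true(all(ch$bundle$repeats$end <= 4e5))
  gs <- vapply(ch$bundle$genes, `[[`, numeric(1), "start")
  ge <- vapply(ch$bundle$genes, `[[`, numeric(1), "end")
  expect_true(all(ge <= 15e4 | gs >= 25e4))

  expect_error(simulate_chromosome(length = 4e5,
                                   centromere_span = c(100, 2e5),
                                   telomere_copies = 100),
               "telomeric caps")
  expect_error(simulate_chromosome(monomer_length = 10), "monomer_length")
})

test_that("generated genomes pass the package's own readers", {
  ch <- simulate_chromosome(length = 3e5, centromere_span = c(1e5, 2e5),
                            telomere_copies = 20, seed = 6)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fasta(ch$bundle$assembly, fa)
  write_gff3(ch$bundle$genes, gff)
  write_repeat_bed(ch$bundle$repeats, bed)
  expect_identical(read_fasta(fa), ch$bundle$assembly)
  back <- read_gff3(gff)
  expect_equal(length(back), length(ch$bundle$genes))
  expect_equal(back[[1]]$start, ch$bundle$genes[[1]]$start)
  rb <- read_repeat_bed(bed)
  expect_equal(rb$start, ch$bundle$repeats$start)
  expect_equal(rb$class, ch$bundle$repeats$class)
})

test_that("SV generator honours design, floors and determinism", {
  ch <- simulate_chromosome(length = 5e5, centromere_span = c(2e5, 3e5),
                            seed = 9)
  acc <- c("t1", "t2", "t3", "ancA", "ancB")
  des <- list(target = c("t1", "t2", "t3"), ancestor_a = "ancA",
              ancestor_b = "ancB")
  sv <- simulate_sv_landscape(acc, des, n_svs = 300,
                              annotation_bundle = ch$bundle, seed = 12)
  expect_identical(sv, simulate_sv_landscape(acc, des, n_svs = 300,
                                             annotation_bundle = ch$bundle,
                                             seed = 12))
  rec <- sv$records
  expect_true(all(rec$length > 20))
  expect_true(all(rec$type %in% c("DEL", "INS", "DUP", "INV", "TRA")))
  expect_true(all(rec$end[rec$type == "INS"] == rec$start[rec$type == "INS"]))
  # every true SV is carried by the whole target group
  for (t in des$target)
    expect_equal(sum(rec$accession == t), 300)
  # ancestor call-set sizes follow the origin structure
  org <- table(sv$manifest$true_sv_origin)
  expect_equal(sum(rec$accession == "ancA"),
               sum(org[c("onlyA", "both")]))
  expect_equal(sum(rec$accession == "ancB"),
               sum(org[c("onlyB", "both")]))
  # records survive the TSV reader round trip with nothing filtered
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sv_table(rec, tsv)
  back <- read_sv_table(tsv, "tsv")
  expect_equal(nrow(back), nrow(rec))

  expect_error(
    simulate_sv_landscape(acc, des, n_svs = 10, repeat_enrichment_factor = 3,
                          annotation_bundle = list(assembly = c(c1 = 1e5),
                                                   repeats = NULL)),
    "repeat annotations required")
})

test_that("SV midpoints are enriched in repeats by the requested factor", {
  ch <- simulate_chromosome(length = 1e6, centromere_span = c(4e5, 6e5),
                            seed = 14)
  acc <- "t1"
  des <- list(target = "t1", ancestor_a = "t1", ancestor_b = "t1",
              origin_proportions = c(onlyA = 0, onlyB = 0, both = 0,
                                     novel = 1))
  sv <- simulate_sv_landscape(acc, des, n_svs = 3000,
                              repeat_enrichment_factor = 4,
                              annotation_bundle = ch$bundle, seed = 15)
  reps <- ch$bundle$repeats
  mask <- IRanges::reduce(IRanges::IRanges(reps$start + 1, reps$end))
  R <- sum(IRanges::width(mask))
  NR <- 1e6 - R
  mid <- with(sv$manifest$true_positions,
              ifelse(type == "INS", start, (start + end) %/% 2))
  hit <- IRanges::overlapsAny(IRanges::IRanges(mid + 1, width = 1), mask)
  expected <- 4 * R / (4 * R + NR)
  expect_lt(abs(mean(hit) - expected),
            3 * sqrt(expected * (1 - expected) / 3000))
})
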