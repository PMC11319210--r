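# Tandem-repeat detection, monomer clustering, centromere scoring and
# telomere scans.

test_that("pure telomeric arrays are found with exact period and copies", {
  seq10 <- strrep("CCCTAAA", 10)
  ar <- find_tandem_repeats(seq10, min_copies = 5)
  expect_equal(nrow(ar), 1L)
  expect_equal(ar$period, 7L)
  expect_equal(ar$copy_number, 10)
  expect_equal(ar$mean_identity, 1.0)
  expect_equal(ar$consensus_monomer, "CCCTAAA")
})

test_that("the smallest valid period is reported, not a multiple", {
  ar <- find_tandem_repeats("ACGTACGTACGT", min_period = 2, min_copies = 3)
  expect_equal(nrow(ar), 1L)
  expect_equal(ar$period, 4L)
  expect_equal(ar$copy_number, 3)
})

test_that("repeat-free sequence yields no arrays", {
  set.seed(5)
  expect_equal(nrow(find_tandem_repeats(random_dna(5000))), 0L)
})

test_that("mutated embedded arrays are localized within one monomer", {
  set.seed(41)
  for (s in 1:3) {
    monomer <- random_dna(100)
    array <- mutate_sequence(strrep(monomer, 50), 0.02)
    left <- random_dna(2000)
    seqfull <- paste0(left, array, random_dna(2000))
    truth <- c(2000, 2000 + 5000)
    ar <- find_tandem_repeats(seqfull, max_period = 250)
    ar <- ar[order(-ar$copy_number), , drop = FALSE]
    expect_gte(nrow(ar), 1L)
    expect_lte(abs(ar$start[1] - truth[1]), 100)
    expect_lte(abs(ar$end[1] - truth[2]), 100)
    oracle_p <- brute_period(seqfull, ar$start[1], ar$end[1])
    expect_lte(abs(ar$period[1] - oracle_p), 2)
    # at zero divergence the detected period is exact
    clean <- paste0(left, strrep(monomer, 50), random_dna(500))
    arc <- find_tandem_repeats(clean, max_period = 250)
    arc <- arc[order(-arc$copy_number), , drop = FALSE]
    expect_equal(arc$period[1], 100L)
  }
})

test_that("reported arrays never overlap and conserve copy counts", {
  set.seed(43)
  seqfull <- paste0(random_dna(1000), strrep(random_dna(80), 20),
                    random_dna(500), strrep("CCCTAAA", 30), random_dna(800))
  ar <- find_tandem_repeats(seqfull)
  if (nrow(ar) > 1) {
    ord <- order(ar$start)
    expect_true(all(ar$start[ord][-1] >= ar$end[ord][-nrow(ar)]))
  }
  cl <- cluster_monomers(array_monomers(ar))
  expect_equal(sum(cl$abundance), sum(ar$copy_number))
})

test_that("monomer clustering merges by identity threshold", {
  # identical monomers collapse into one cluster with summed abundance
  mono <- data.frame(array_id = 1:3, monomer = rep("ACGTACGTAA", 3),
                     copy_number = c(10, 20, 30))
  cl <- cluster_monomers(mono)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$abundance, 60)

  # two families at ~70% identity: split at threshold 0.8, merged at 0.6
  set.seed(47)
  base <- random_dna(100)
  other <- mutate_positions(base, sample.int(100, 30))
  expect_lt(1 - monomer_distance(base, other), 0.8)
  expect_gt(1 - monomer_distance(base, other), 0.6)
  fams <- data.frame(
    array_id = 1:6,
    monomer = c(base, mutate_sequence(base, 0.02), mutate_sequence(base, 0.02),
                other, mutate_sequence(other, 0.02),
                mutate_sequence(other, 0.02)),
    copy_number = rep(5, 6))
  expect_equal(nrow(cluster_monomers(fams, identity_threshold = 0.8)), 2L)
  expect_equal(nrow(cluster_monomers(fams, identity_threshold = 0.6)), 1L)

  # reverse-complement monomers belong to the same cluster
  rcpair <- data.frame(array_id = 1:2,
                       monomer = c(base, revcomp(base)),
                       copy_number = c(1, 1))
  expect_equal(nrow(cluster_monomers(rcpair)), 1L)

  # top_clusters caps at k ranked by abundance
  many <- data.frame(array_id = 1:12,
                     monomer = vapply(1:12, function(i) random_dna(60),
                                      character(1)),
                     copy_number = 12:1)
  cl12 <- cluster_monomers(many)
  expect_lte(nrow(top_clusters(cl12, 8)), 8L)
  expect_equal(top_clusters(cl12, 8)$abundance,
               sort(cl12$abundance, decreasing = TRUE)[1:8])
})

test_that("centromere calls recover the simulated span", {
  ch <- simulate_chromosome(length = 1e6, centromere_span = c(35e4, 65e4),
                            seed = 19)
  ar <- find_tandem_repeats(ch$sequence)
  cl <- cluster_monomers(array_monomers(ar))
  cc <- call_centromere(1e6, ar, cl, ch$bundle$genes, ch$bundle$repeats,
                        window = 5e4, step = 2.5e4)
  expect_false(is.null(cc))
  expect_gte(jaccard_span(cc$span, ch$manifest$true_centromere), 0.8)
  expect_equal(cc$dominant_cluster, 1L)

  # repeat-free chromosome: no candidate windows, no call
  set.seed(3)
  bare <- random_dna(3e5)
  ar0 <- find_tandem_repeats(bare)
  cc0 <- call_centromere(3e5, ar0,
                         if (nrow(ar0)) cluster_monomers(array_monomers(ar0))
                         else data.frame(),
                         window = 5e4, step = 2.5e4)
  expect_null(cc0)
})

test_that("gene-poor Gypsy-rich arrays beat gene-dense ones", {
  # two identical-coverage arrays; evidence must disambiguate
  arrays <- data.frame(start = c(2e5, 6e5), end = c(3e5, 7e5),
                       period = c(100L, 100L), copy_number = c(1000, 1000),
                       mean_identity = c(1, 1),
                       consensus_monomer = c(random_dna(100), random_dna(100)))
  cl <- cluster_monomers(array_monomers(arrays))
  genes <- lapply(seq(150000, 350000, by = 7000), function(s)
    list(id = paste0("g", s), chromosome = "c", start = s, end = s + 3000,
         strand = "+", cds_parts = cbind(start = s, end = s + 1500)))
  repeats <- data.frame(chromosome = "c", start = 590000, end = 710000,
                        class = "LTR/Gypsy")
  cc <- call_centromere(1e6, arrays, cl, genes, repeats,
                        window = 5e4, step = 5e4)
  expect_gte(jaccard_span(cc$span, c(6e5, 7e5)), 0.8)
})

test_that("telomere detection is end-specific and strand-consistent", {
  set.seed(29)
  core <- random_dna(4e4)
  both <- paste0(strrep("CCCTAAA", 100), core, strrep("TTTAGGG", 100))
  tl <- detect_telomeres(both)
  expect_equal(tl$present, c(TRUE, TRUE))
  expect_gte(min(tl$motif_copies), 100)

  none <- detect_telomeres(core)
  expect_equal(sum(none$present), 0L)

  five_only <- detect_telomeres(paste0(strrep("CCCTAAA", 50), core))
  expect_equal(five_only$present, c(TRUE, FALSE))

  # reverse-complementing the chromosome swaps the two calls
  rc <- detect_telomeres(revcomp(five_only_seq <- paste0(
    strrep("CCCTAAA", 50), core)))
  expect_equal(rc$present, c(FALSE, TRUE))
})

test_that("centromere calls mirror under reverse complement", {
  ch <- simulate_chromosome(length = 6e5, centromere_span = c(2e5, 4e5),
                            seed = 53, telomere_copies = 50)
  len <- nchar(ch$sequence)
  scan_call <- function(s) {
    ar <- find_tandem_repeats(s)
    cl <- cluster_monomers(array_monomers(ar))
    call_centromere(len, ar, cl, window = 5e4, step = 2.5e4)
  }
  fwd <- scan_call(ch$sequence)
  rev <- scan_call(revcomp(ch$sequence))
  mirrored <- c(len - rev$span[2], len - rev$span[1])
  expect_gte(jaccard_span(fwd$span, mirrored), 0.9)
})
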