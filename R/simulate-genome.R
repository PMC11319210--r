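# Synthetic chromosome generator: telomeric (CCCTAAA)n caps, a centromeric
# tandem array of a random monomer with per-base divergence, Gypsy-labelled
# repeats enriched inside the centromere, and genes outside it.
#
# Defaults are desk-scale study conditions: a 2 Mb chromosome with a 500 kb
# centromere (roughly a 15x shrink of a ~30 Mb watermelon chromosome keeping
# the centromere proportion), a 100 bp monomer at 5% divergence, and 100
# telomere copies per end.

TELOMERE_MOTIF <- "CCCTAAA"

#' Simulate a chromosome with known centromere and telomeres
#'
#' @param length chromosome length in bp.
#' @param centromere_span numeric length-2, 0-based half-open span of the
#'   centromeric array; must not touch the telomeric caps.
#' @param monomer_length monomer size in bp (50..2000).
#' @param monomer_divergence per-base substitution rate applied independently
#'   to every monomer copy.
#' @param gypsy_enrichment multiplicative density factor for Gypsy elements
#'   inside the centromere relative to the chromosome arms.
#' @param gene_density genes per Mb on the chromosome arms.
#' @param telomere_copies copies of CCCTAAA at the 5' end (its reverse
#'   complement at the 3' end).
#' @param gypsy_per_mb baseline Gypsy elements per Mb on the arms.
#' @param chrom_name chromosome id used in the annotation bundle.
#' @param seed integer seed.
#' @return list with `sequence`, `bundle` (list: `assembly`, `genes`,
#'   `repeats`) and `manifest` (list: `seed`, `true_centromere`,
#'   `true_monomer`, `true_telomere_ends`, `generator_params`).
#' @export
simulate_chromosome <- function(length = 2e6,
                                centromere_span = c(750000, 1250000),
                                monomer_length = 100L,
                                monomer_divergence = 0.05,
                                gypsy_enrichment = 5,
                                gene_density = 65,
                                telomere_copies = 100L,
                                gypsy_per_mb = 10,
                                chrom_name = "chr01",
                                seed = 1L) {
  length <- as.integer(length)
  cs <- as.integer(centromere_span[1])
  ce <- as.integer(centromere_span[2])
  tl <- 7L * telomere_copies
  if (monomer_length < 50L || monomer_length > 2000L)
    stop_input("monomer_length must be in [50, 2000]")
  if (cs < 0L || ce > length || cs >= ce)
    stop_input("centromere_span must lie within [0, length)")
  if (cs < tl || ce > length - tl)
    stop_input("centromere_span overlaps the telomeric caps")
  set.seed(seed)

  telo5 <- strrep(TELOMERE_MOTIF, telomere_copies)
  telo3 <- strrep(revcomp(TELOMERE_MOTIF), telomere_copies)
  monomer <- random_dna(monomer_length)
  cen_len <- ce - cs
  n_copies <- ceiling(cen_len / monomer_length)
  cen_seq <- substr(strrep(monomer, n_copies), 1L, cen_len)
  cen_seq <- mutate_sequence(cen_seq, monomer_divergence)

  arm1 <- random_dna(cs - tl)
  arm2 <- random_dna(length - ce - tl)
  sequence <- paste0(telo5, arm1, cen_seq, arm2, telo3)
  stopifnot(nchar(sequence) == length)

  # repeat annotations: the satellite array, plus Gypsy elements enriched
  # inside the centromere and a Copia background on the arms
  repeats <- data.frame(chromosome = character(), start = integer(),
                        end = integer(), class = character(),
                        stringsAsFactors = FALSE)
  add_elements <- function(n, lo, hi, cls, len_range = c(2000L, 8000L)) {
    if (n <= 0L || hi - lo < len_range[2]) return(NULL)
    len <- as.integer(runif(n, len_range[1], len_range[2]))
    st <- as.integer(runif(n, lo, hi - len))
    data.frame(chromosome = chrom_name, start = st, end = st + len,
               class = cls, stringsAsFactors = FALSE)
  }
  arm_mb <- (length - cen_len - 2 * tl) / 1e6
  n_gy_arm <- stats::rpois(1L, gypsy_per_mb * arm_mb)
  n_gy_cen <- stats::rpois(1L, gypsy_per_mb * gypsy_enrichment * cen_len / 1e6)
  n_copia <- stats::rpois(1L, gypsy_per_mb * arm_mb)
  arm_elements <- function(n, cls) {
    if (n <= 0L) return(NULL)
    split_n <- rbinom(1L, n, (cs - tl) / (length - cen_len - 2 * tl))
    rbind(add_elements(split_n, tl, cs, cls),
          add_elements(n - split_n, ce, length - tl, cls))
  }
  repeats <- rbind(
    data.frame(chromosome = chrom_name, start = cs, end = ce,
               class = "Satellite/centromeric", stringsAsFactors = FALSE),
    arm_elements(n_gy_arm, "LTR/Gypsy"),
    add_elements(n_gy_cen, cs, ce, "LTR/Gypsy"),
    arm_elements(n_copia, "LTR/Copia"))
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  # genes on the arms only
  n_genes <- stats::rpois(1L, gene_density * arm_mb)
  genes <- list()
  for (i in seq_len(n_genes)) {
    glen <- as.integer(runif(1L, 1000L, 5000L))
    on_left <- runif(1L) < (cs - tl) / (length - cen_len - 2 * tl)
    lo <- if (on_left) tl else ce
    hi <- if (on_left) cs else length - tl
    if (hi - lo <= glen) next
    gs <- as.integer(runif(1L, lo, hi - glen))
    strand <- sample(c("+", "-"), 1L)
    n_cds <- sample(1:3, 1L)
    bounds <- sort(as.integer(runif(2L * n_cds, gs, gs + glen)))
    parts <- cbind(start = bounds[seq(1L, 2L * n_cds, by = 2L)],
                   end = bounds[seq(2L, 2L * n_cds, by = 2L)])
    parts <- parts[parts[, "end"] > parts[, "start"], , drop = FALSE]
    if (nrow(parts) == 0L)
      parts <- cbind(start = gs, end = gs + glen)
    if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
    genes[[length(genes) + 1L]] <- list(
      id = sprintf("%s_g%04d", chrom_name, length(genes) + 1L),
      chromosome = chrom_name, start = gs, end = gs + glen,
      strand = strand, cds_parts = parts)
  }

  list(sequence = sequence,
       bundle = list(assembly = stats::setNames(sequence, chrom_name),
                     genes = genes, repeats = repeats),
       manifest = list(seed = seed,
                       true_centromere = c(cs, ce),
                       true_monomer = monomer,
                       true_telomere_ends = 2L,
                       generator_params = list(
                         length = length, monomer_length = monomer_length,
                         monomer_divergence = monomer_divergence,
                         gypsy_enrichment = gypsy_enrichment,
                         gene_density = gene_density,
                         telomere_copies = telomere_copies)))
}

#' Simulate a multi-chromosome genome
#'
#' Applies [simulate_chromosome()] per chromosome with derived sub-seeds and
#' pools the annotation bundles and manifests.
#'
#' @param n_chromosomes number of chromosomes (a watermelon-like genome has
#'   11).
#' @param seed integer seed; chromosome i uses `seed + 1000 * i`.
#' @param ... passed to [simulate_chromosome()] (except `chrom_name`/`seed`).
#' @return list with `bundle` (pooled `assembly`, `genes`, `repeats`) and
#'   `manifests` (per-chromosome list).
#' @export
simulate_genome <- function(n_chromosomes = 11L, seed = 1L, ...) {
  chroms <- lapply(seq_len(n_chromosomes), function(i)
    simulate_chromosome(chrom_name = sprintf("chr%02d", i),
                        seed = seed + 1000L * i, ...))
  assembly <- unlist(lapply(chroms, function(x) x$bundle$assembly))
  genes <- do.call(c, lapply(chroms, function(x) x$bundle$genes))
  repeats <- do.call(rbind, lapply(chroms, function(x) x$bundle$repeats))
  manifests <- lapply(chroms, `[[`, "manifest")
  names(manifests) <- names(assembly)
  list(bundle = list(assembly = assembly, genes = genes, repeats = repeats),
       manifests = manifests)
}
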