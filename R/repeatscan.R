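# Tandem-repeat detection, monomer clustering, centromere scoring and
# telomere scanning.
#
# Detection replaces a probabilistic-alignment repeat finder with a
# transparent two-stage procedure: (1) candidate periods from the distances
# between re-occurring k-mer seeds, (2) verification and greedy monomer-wise
# extension under a shifted-self identity threshold. Period multiples are
# collapsed to the smallest divisor that still satisfies the identity
# threshold, so a dimer of the true monomer is never reported.

#' Detect tandem-repeat arrays in a sequence
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param min_period,max_period period search range in bp.
#' @param min_copies minimum copy number for a reported array.
#' @param min_identity minimum fraction of matching bases between the array
#'   and itself shifted by one period.
#' @return data.frame with one row per array: `start`, `end` (0-based
#'   half-open), `period`, `copy_number`, `mean_identity`,
#'   `consensus_monomer`. Arrays never overlap (overlaps are merged keeping
#'   the higher-scoring one). Empty data.frame on repeat-free input.
#' @export
find_tandem_repeats <- function(sequence, min_period = 5L, max_period = 500L,
                                min_copies = 5L, min_identity = 0.8) {
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), mean_identity = numeric(),
                      consensus_monomer = character(),
                      stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n < 2L * min_period) return(empty)
  x <- seq_codes(sequence)

  # --- seed stage: positions where the same k-mer re-occurs at a distance
  # inside the period range
  k <- max(4L, min(12L, min_period + 4L))
  k <- min(k, n - min_period)
  if (k < 2L) return(empty)
  np <- n - k + 1L
  h <- numeric(np)
  for (jj in 0:(k - 1L)) h <- h * 13 + x[(1L + jj):(np + jj)]
  o <- order(h, seq_len(np))
  same <- diff(h[o]) == 0
  p1 <- o[-length(o)][same]
  p2 <- o[-1L][same]
  dd <- p2 - p1
  sel <- dd >= min_period & dd <= max_period
  cand <- data.frame(pos = p1[sel], period = dd[sel])
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$pos, cand$period), , drop = FALSE]

  shifted_identity <- function(a, b, p) {
    # identity of x[a..b] against itself shifted by p (requires b + p <= n)
    mean(x[a:b] == x[(a + p):(b + p)])
  }

  covered <- logical(n)
  arrays <- list()
  cand_pos <- cand$pos
  cand_per <- cand$period
  for (idx in seq_along(cand_pos)) {
    p0 <- cand_pos[idx]
    per <- cand_per[idx]
    if (covered[p0]) next
    # verify: one period of support shifted against the next
    if (p0 + 2L * per - 1L > n) next
    if (shifted_identity(p0, p0 + per - 1L, per) < min_identity) next
    s <- p0
    e <- p0 + 2L * per - 1L
    # extend right monomer-by-monomer
    while (e + per <= n &&
           shifted_identity(e - per + 1L, e, per) >= min_identity)
      e <- e + per
    # extend left
    while (s - per >= 1L &&
           shifted_identity(s - per, s - 1L, per) >= min_identity)
      s <- s - per
    copies <- (e - s + 1L) / per
    if (copies < min_copies) next
    # collapse to the smallest divisor period that still verifies
    divs <- seq_len(per %/% 2L)
    divs <- divs[per %% divs == 0L & divs >= min_period]
    for (p2 in divs) {
      if (shifted_identity(s, e - p2, p2) >= min_identity) {
        per <- p2
        copies <- (e - s + 1L) / per
        break
      }
    }
    ident <- shifted_identity(s, e - per, per)
    arrays[[length(arrays) + 1L]] <-
      list(s = s, e = e, period = per, copies = copies, identity = ident)
    covered[s:e] <- TRUE
  }
  if (length(arrays) == 0L) return(empty)

  df <- do.call(rbind, lapply(arrays, function(a)
    data.frame(start = a$s - 1L, end = a$e, period = a$period,
               copy_number = a$copies, mean_identity = a$identity,
               stringsAsFactors = FALSE)))
  df <- df[order(df$start), , drop = FALSE]

  # merge overlaps, keeping the higher-scoring (copies * identity) array
  kept <- df[1, , drop = FALSE]
  if (nrow(df) > 1L) {
    for (i in 2:nrow(df)) {
      last <- nrow(kept)
      if (df$start[i] < kept$end[last]) {
        score_new <- df$copy_number[i] * df$mean_identity[i]
        score_old <- kept$copy_number[last] * kept$mean_identity[last]
        if (score_new > score_old) kept[last, ] <- df[i, ]
      } else {
        kept <- rbind(kept, df[i, ])
      }
    }
  }
  kept$consensus_monomer <- vapply(seq_len(nrow(kept)), function(i)
    .consensus_monomer(x, kept$start[i] + 1L, kept$end[i], kept$period[i]),
    character(1))
  rownames(kept) <- NULL
  kept
}

# majority-vote consensus across the full monomer copies of an array
.consensus_monomer <- function(x, s, e, per) {
  ncopy <- (e - s + 1L) %/% per
  if (ncopy < 1L) return("")
  mat <- matrix(x[s:(s + ncopy * per - 1L)], nrow = per)
  bases <- c("A", "C", "G", "T", "N")
  cons <- apply(mat, 1L, function(v) {
    tb <- tabulate(v, nbins = 5L)
    bases[which.max(tb)]
  })
  paste(cons, collapse = "")
}

#' Monomer table from detected arrays
#'
#' Convenience bridge between [find_tandem_repeats()] and
#' [cluster_monomers()]: one monomer (the array consensus) per array, with
#' `array_id` equal to the array's row index.
#'
#' @param arrays a [find_tandem_repeats()] result.
#' @return data.frame with columns `array_id`, `monomer`, `copy_number`.
#' @export
array_monomers <- function(arrays) {
  data.frame(array_id = seq_len(nrow(arrays)),
             monomer = arrays$consensus_monomer,
             copy_number = arrays$copy_number,
             stringsAsFactors = FALSE)
}

#' Greedy identity clustering of tandem-repeat monomers
#'
#' Monomers are processed by decreasing length; each joins the first cluster
#' whose representative is within the identity threshold (both strands
#' tried), otherwise it founds a new cluster. Cluster abundance is the sum of
#' member array copy numbers and ranks are assigned by decreasing abundance.
#'
#' @param monomers data.frame with columns `array_id`, `monomer` (consensus
#'   sequence) and `copy_number` (as produced from [find_tandem_repeats()]
#'   output).
#' @param identity_threshold minimum identity (`1 - normalized edit
#'   distance`) to the cluster representative.
#' @return data.frame of clusters: `rank`, `representative`, `abundance`,
#'   `n_members`; attribute `"members"` maps cluster rank to member
#'   `array_id`s.
#' @export
cluster_monomers <- function(monomers, identity_threshold = 0.8) {
  stopifnot(nrow(monomers) >= 1L,
            all(c("array_id", "monomer", "copy_number") %in% names(monomers)))
  ord <- order(nchar(monomers$monomer), decreasing = TRUE)
  mono <- monomers[ord, , drop = FALSE]
  reps <- character(0)
  members <- list()
  abundance <- numeric(0)
  for (i in seq_len(nrow(mono))) {
    seq_i <- mono$monomer[i]
    rc_i <- revcomp(seq_i)
    joined <- FALSE
    for (cl in seq_along(reps)) {
      ident <- 1 - min(monomer_distance(seq_i, reps[cl]),
                       monomer_distance(rc_i, reps[cl]))
      if (ident >= identity_threshold) {
        members[[cl]] <- c(members[[cl]], mono$array_id[i])
        abundance[cl] <- abundance[cl] + mono$copy_number[i]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, seq_i)
      members[[length(reps)]] <- mono$array_id[i]
      abundance <- c(abundance, mono$copy_number[i])
    }
  }
  ord2 <- order(-abundance, seq_along(abundance))
  out <- data.frame(rank = seq_along(reps),
                    representative = reps[ord2],
                    abundance = abundance[ord2],
                    n_members = lengths(members)[ord2],
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members[ord2]
  out
}

#' Keep the most abundant monomer clusters
#' @param clusters a [cluster_monomers()] result.
#' @param k maximum number of clusters to keep (centromere analyses typically count the top 8).
#' @return the top `k` rows (fewer when fewer exist), members attribute
#'   subset accordingly.
#' @export
top_clusters <- function(clusters, k = 8L) {
  keep <- seq_len(min(k, nrow(clusters)))
  out <- clusters[keep, , drop = FALSE]
  attr(out, "members") <- attr(clusters, "members")[keep]
  out
}

#' Call the centromere of a chromosome from integrated evidence
#'
#' Windows tiling the chromosome are scored as
#' `w1 * monomer-coverage + w2 * Gypsy-bp-fraction - w3 * gene-count/max`,
#' where monomer coverage counts bp covered by arrays belonging to the top
#' monomer clusters. Candidate regions are maximal runs of consecutive
#' windows with monomer coverage >= `c_min`; the run with the highest mean
#' score wins (ties to the leftmost), giving one call per chromosome
#' (monocentric assumption) or none.
#'
#' @param chrom_length chromosome length in bp.
#' @param arrays [find_tandem_repeats()] output for the chromosome (rows are
#'   implicitly array ids 1..n in order).
#' @param clusters [cluster_monomers()] result over those arrays (already
#'   restricted via [top_clusters()] if desired).
#' @param genes list of gene models on the chromosome (may be empty).
#' @param repeats repeat annotation data.frame for the chromosome (columns
#'   `start`, `end`, `class`); Gypsy elements are rows whose class matches
#'   "Gypsy".
#' @param window,step window size and step in bp.
#' @param weights numeric length-3: monomer, Gypsy and gene-penalty weights.
#' @param c_min minimum per-window monomer coverage for candidate windows.
#' @param top_k number of top clusters whose arrays count as centromeric.
#' @return list with `span` (0-based half-open), `score`, `dominant_cluster`
#'   (rank) and `evidence` (per-window data.frame), or `NULL` when no
#'   candidate run exists.
#' @export
call_centromere <- function(chrom_length, arrays, clusters, genes = list(),
                            repeats = NULL, window = 1e5, step = 5e4,
                            weights = c(1.0, 0.3, 0.3), c_min = 0.3,
                            top_k = 8L) {
  stopifnot(chrom_length > 0, window > 0, step > 0, length(weights) == 3L)
  starts <- seq(0, max(0, chrom_length - window), by = step)
  wr <- as_iranges0(starts, pmin(starts + window, chrom_length))

  cov_frac <- numeric(length(starts))
  dominant <- NA_integer_
  if (nrow(arrays) > 0L) {
    top <- top_clusters(clusters, top_k)
    top_ids <- unlist(attr(top, "members"))
    use <- arrays[seq_len(nrow(arrays)) %in% top_ids, , drop = FALSE]
    if (nrow(use) > 0L) {
      ar <- as_iranges0(use$start, use$end)
      ov <- IRanges::findOverlaps(wr, ar)
      if (length(ov) > 0L) {
        inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                     ar[S4Vectors::subjectHits(ov)])
        bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
        cov_frac[as.integer(names(bp))] <- bp / IRanges::width(wr)[as.integer(names(bp))]
      }
    }
  }

  gypsy_frac <- numeric(length(starts))
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    gy <- repeats[grepl("Gypsy", repeats$class), , drop = FALSE]
    if (nrow(gy) > 0L) {
      gr <- IRanges::reduce(as_iranges0(gy$start, gy$end))
      ov <- IRanges::findOverlaps(wr, gr)
      if (length(ov) > 0L) {
        inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                     gr[S4Vectors::subjectHits(ov)])
        bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
        gypsy_frac[as.integer(names(bp))] <- bp / IRanges::width(wr)[as.integer(names(bp))]
      }
    }
  }

  gene_count <- numeric(length(starts))
  if (length(genes) > 0L) {
    gs <- vapply(genes, `[[`, numeric(1), "start")
    ge <- vapply(genes, `[[`, numeric(1), "end")
    gr <- as_iranges0(gs, ge)
    gene_count <- IRanges::countOverlaps(wr, gr)
  }
  gene_pen <- if (max(gene_count) > 0) gene_count / max(gene_count)
              else numeric(length(starts))

  score <- weights[1] * cov_frac + weights[2] * gypsy_frac -
           weights[3] * gene_pen
  evidence <- data.frame(window_start = starts,
                         window_end = pmin(starts + window, chrom_length),
                         monomer_coverage = cov_frac,
                         gypsy_fraction = gypsy_frac,
                         gene_count = as.numeric(gene_count),
                         score = score)

  above <- cov_frac >= c_min
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends_i <- cumsum(runs$lengths)
  starts_i <- ends_i - runs$lengths + 1L
  cand <- which(runs$values)
  best <- NULL
  for (ci in cand) {
    idx <- starts_i[ci]:ends_i[ci]
    mscore <- mean(score[idx])
    if (is.null(best) || mscore > best$mscore)
      best <- list(idx = idx, mscore = mscore)
  }
  span <- c(evidence$window_start[best$idx[1]],
            evidence$window_end[best$idx[length(best$idx)]])
  if (nrow(arrays) > 0L) {
    # dominant cluster: the top cluster with most abundance inside the span
    top <- top_clusters(clusters, top_k)
    mem <- attr(top, "members")
    in_span <- which(arrays$start < span[2] & arrays$end > span[1])
    ab <- vapply(mem, function(ids)
      sum(arrays$copy_number[intersect(ids, in_span)]), numeric(1))
    if (any(ab > 0)) dominant <- top$rank[which.max(ab)]
  }
  list(span = span, score = best$mscore, dominant_cluster = dominant,
       evidence = evidence)
}

#' Scan chromosome ends for telomeric repeats
#'
#' Counts copies of the plant telomere motif (default `CCCTAAA`) in the 5'
#' terminal window and of its reverse complement (`TTTAGGG`) in the 3'
#' terminal window. An end is telomere-positive when the copy count reaches
#' `min_copies`.
#'
#' @param sequence chromosome sequence (length > 2 * `terminal_window`).
#' @param motif telomeric repeat unit expected at the 5' end.
#' @param terminal_window bp scanned at each end.
#' @param min_copies copy threshold for presence.
#' @return data.frame with rows `5prime` and `3prime`: columns `end`,
#'   `motif_copies`, `present`.
#' @export
detect_telomeres <- function(sequence, motif = "CCCTAAA",
                             terminal_window = 1e4, min_copies = 10L) {
  n <- nchar(sequence)
  if (n <= 2 * terminal_window)
    stop_input("sequence must be longer than twice the terminal window")
  five <- substr(sequence, 1L, terminal_window)
  three <- substr(sequence, n - terminal_window + 1L, n)
  c5 <- Biostrings::countPattern(motif, Biostrings::DNAString(five))
  c3 <- Biostrings::countPattern(revcomp(motif), Biostrings::DNAString(three))
  data.frame(end = c("5prime", "3prime"),
             motif_copies = c(c5, c3),
             present = c(c5, c3) >= min_copies,
             stringsAsFactors = FALSE)
}

#' Count telomeres across a genome
#' @param assembly named character vector of chromosome sequences.
#' @param ... passed to [detect_telomeres()].
#' @return integer: number of telomere-positive chromosome ends.
#' @export
count_telomeres <- function(assembly, ...) {
  sum(vapply(assembly, function(s) sum(detect_telomeres(s, ...)$present),
             numeric(1)))
}
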