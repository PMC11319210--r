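# Structural-variant landscape analysis: cross-accession merging into a
# nonredundant set, type summaries, genomic-context annotation, repeat
# enrichment, inversion hotspots and two-ancestor inheritance partitioning.
#
# Merge criterion (community-standard, SURVIVOR/truvari-like defaults):
# same-chromosome, same-type records merge when
#   DEL/DUP/INV : reciprocal overlap >= `reciprocal_overlap` (both ways),
#   INS         : anchor points within `ins_window` bp and
#                 min(length)/max(length) >= `ins_len_ratio`,
#   TRA         : both breakpoints within `ins_window` bp,
# taking connected components of the pairwise relation. The representative
# is the member with the (lower) median length.

#' Merge per-accession SV call sets into a nonredundant set
#'
#' @param svs data.frame of per-accession records (see [read_sv_table()]).
#' @param reciprocal_overlap reciprocal-overlap threshold for DEL/DUP/INV.
#' @param ins_window breakpoint distance window (bp) for INS and TRA.
#' @param ins_len_ratio minimum length ratio for INS merging.
#' @return object of class `nr_sv_set`: list with `table` (data.frame `id`,
#'   `chromosome`, `start`, `end`, `type`, `length`, `n_members`) and
#'   `presence` (logical matrix, records x accessions).
#' @export
merge_svs <- function(svs, reciprocal_overlap = 0.5, ins_window = 100L,
                      ins_len_ratio = 0.5) {
  stopifnot(all(c("accession", "chromosome", "start", "end",
                  "type", "length") %in% names(svs)))
  if (nrow(svs) == 0L) stop_input("no SV records to merge")
  if (any(!svs$type %in% .sv_types)) stop_input("unknown SV type")
  accessions <- sort(unique(svs$accession))
  groups <- split(seq_len(nrow(svs)),
                  list(svs$chromosome, svs$type), drop = TRUE)
  rows <- list()
  presence <- list()
  for (g in groups) {
    sub <- svs[g, , drop = FALSE]
    comp <- .sv_components(sub, reciprocal_overlap, ins_window, ins_len_ratio)
    for (cid in unique(comp)) {
      mem <- sub[comp == cid, , drop = FALSE]
      # representative: member with the (lower) median length; stable ties
      med <- sort(mem$length)[ceiling(nrow(mem) / 2)]
      rep_i <- which(mem$length == med)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = mem$chromosome[rep_i], start = mem$start[rep_i],
        end = mem$end[rep_i], type = mem$type[rep_i],
        length = mem$length[rep_i], n_members = nrow(mem),
        stringsAsFactors = FALSE)
      presence[[length(rows)]] <- accessions %in% mem$accession
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$chromosome, tab$start, tab$type)
  tab <- tab[ord, , drop = FALSE]
  pm <- do.call(rbind, presence)[ord, , drop = FALSE]
  colnames(pm) <- accessions
  tab$id <- sprintf("sv%06d", seq_len(nrow(tab)))
  rownames(tab) <- rownames(pm) <- tab$id
  structure(list(table = tab[, c("id", "chromosome", "start", "end", "type",
                                 "length", "n_members")],
                 presence = pm),
            class = "nr_sv_set")
}

# connected components of the pairwise merge relation within one
# chromosome x type group
.sv_components <- function(sub, ro, win, lr) {
  n <- nrow(sub)
  if (n == 1L) return(1L)
  type <- sub$type[1]
  if (type %in% c("DEL", "DUP", "INV")) {
    ir <- as_iranges0(sub$start, sub$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (length(qi)) {
      inter <- pmin(sub$end[qi], sub$end[si]) - pmax(sub$start[qi], sub$start[si])
      len_q <- sub$end[qi] - sub$start[qi]
      len_s <- sub$end[si] - sub$start[si]
      ok <- inter >= ro * len_q & inter >= ro * len_s
      qi <- qi[ok]; si <- si[ok]
    }
  } else if (type == "INS") {
    pairs <- .near_pairs(sub$start, win)
    qi <- pairs[, 1]; si <- pairs[, 2]
    if (length(qi)) {
      ok <- pmin(sub$length[qi], sub$length[si]) /
            pmax(sub$length[qi], sub$length[si]) >= lr
      qi <- qi[ok]; si <- si[ok]
    }
  } else { # TRA: both breakpoints within the window
    pairs <- .near_pairs(sub$start, win)
    qi <- pairs[, 1]; si <- pairs[, 2]
    if (length(qi)) {
      ok <- abs(sub$end[qi] - sub$end[si]) <= win
      qi <- qi[ok]; si <- si[ok]
    }
  }
  .components_from_edges(n, qi, si)
}

# connected components by union-find with path halving
.components_from_edges <- function(n, qi, si) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_along(qi)) {
    ra <- find(qi[e]); rb <- find(si[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# index pairs (i < j) with |x_i - x_j| <= win, found on the sorted order
.near_pairs <- function(x, win) {
  n <- length(x)
  o <- order(x)
  out <- list()
  for (a in seq_len(n - 1L)) {
    b <- a + 1L
    while (b <= n && x[o[b]] - x[o[a]] <= win) {
      out[[length(out) + 1L]] <- c(min(o[a], o[b]), max(o[a], o[b]))
      b <- b + 1L
    }
  }
  if (length(out) == 0L) return(matrix(integer(), ncol = 2L))
  do.call(rbind, out)
}

#' @export
print.nr_sv_set <- function(x, ...) {
  cat("Nonredundant SV set:", nrow(x$table), "records over",
      ncol(x$presence), "accessions\n")
  invisible(x)
}

#' Tally a nonredundant SV set by type
#'
#' Percentages are reported as `100 * count / total`, rounded half-up to two
#' decimals (report parity with the five-category landscape summary).
#'
#' @param x an `nr_sv_set`, or a character vector / factor of type codes, or
#'   a named numeric vector of per-type counts.
#' @return data.frame with `type`, `count`, `percent`; attribute `"total"`.
#' @export
summarize_types <- function(x) {
  counts <- if (inherits(x, "nr_sv_set")) table(factor(x$table$type, .sv_types))
            else if (is.numeric(x) && !is.null(names(x))) {
              v <- stats::setNames(numeric(5), .sv_types)
              v[map_sv_type(names(x))] <- x
              v
            } else table(factor(map_sv_type(as.character(x)), .sv_types))
  counts <- stats::setNames(as.numeric(counts), .sv_types)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2L) else counts * 0
  out <- data.frame(type = .sv_types, count = counts, percent = pct,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Annotate nonredundant SVs with genomic context
#'
#' Context precedence: `cds` > `genic_noncds` > `flank2kb` > `intergenic`,
#' decided by any-overlap of the SV span (insertions: anchor point) with CDS
#' parts, gene spans, then gene spans extended by 2 kb. `in_repeat` marks
#' any-overlap with a repeat feature. Coding effect for CDS-overlapping
#' DEL/INS/DUP is `frameshift` when length mod 3 != 0, else `inframe`;
#' CDS-overlapping INV/TRA are `structural`; everything else `none`.
#'
#' @param nr an `nr_sv_set` from [merge_svs()].
#' @param genes list of gene models (see [read_gff3()]); all chromosomes.
#' @param repeats repeat data.frame (`chromosome`, `start`, `end`, `class`).
#' @param flank flank size in bp (2 kb in the landscape analysis).
#' @return list with `annotations` (data.frame: `id`, `context`, `in_repeat`,
#'   `coding_effect`) and `summary` (fractions per context plus
#'   `frac_in_repeat` and `frac_coding_change`). SVs on chromosomes absent
#'   from the annotation are flagged in `excluded` and left out of fractions.
#' @export
annotate_svs <- function(nr, genes, repeats = NULL, flank = 2000L) {
  stopifnot(inherits(nr, "nr_sv_set"))
  tab <- nr$table
  known <- unique(c(
    vapply(genes, `[[`, character(1), "chromosome"),
    if (!is.null(repeats)) repeats$chromosome else character(0)))
  excluded <- tab$id[!tab$chromosome %in% known]
  use <- tab[tab$chromosome %in% known, , drop = FALSE]
  if (nrow(use) == 0L) stop_input("no SVs on annotated chromosomes")

  is_ins <- use$type == "INS"
  qend <- ifelse(is_ins, use$start + 1L, use$end)  # point semantics for INS
  q <- as_granges0(use$chromosome, use$start, qend)

  overlap_any <- function(gr) {
    if (length(gr) == 0L) return(logical(nrow(use)))
    IRanges::overlapsAny(q, gr)
  }
  gene_chr <- vapply(genes, `[[`, character(1), "chromosome")
  gene_s <- vapply(genes, `[[`, numeric(1), "start")
  gene_e <- vapply(genes, `[[`, numeric(1), "end")
  gene_gr <- if (length(genes)) as_granges0(gene_chr, gene_s, gene_e)
             else GenomicRanges::GRanges()
  cds_list <- lapply(genes, function(g) {
    if (nrow(g$cds_parts) == 0L) return(NULL)
    data.frame(chromosome = g$chromosome,
               start = g$cds_parts[, "start"], end = g$cds_parts[, "end"])
  })
  cds_df <- do.call(rbind, cds_list)
  cds_gr <- if (!is.null(cds_df) && nrow(cds_df))
    as_granges0(cds_df$chromosome, cds_df$start, cds_df$end)
    else GenomicRanges::GRanges()
  flank_gr <- if (length(genes))
    as_granges0(gene_chr, pmax(0, gene_s - flank), gene_e + flank)
    else GenomicRanges::GRanges()

  in_cds <- overlap_any(cds_gr)
  in_gene <- overlap_any(gene_gr)
  in_flank <- overlap_any(flank_gr)
  context <- ifelse(in_cds, "cds",
             ifelse(in_gene, "genic_noncds",
             ifelse(in_flank, "flank2kb", "intergenic")))

  in_repeat <- if (!is.null(repeats) && nrow(repeats))
    overlap_any(as_granges0(repeats$chromosome, repeats$start, repeats$end))
    else logical(nrow(use))

  coding <- rep("none", nrow(use))
  coding[in_cds & use$type %in% c("DEL", "INS", "DUP")] <-
    ifelse(use$length[in_cds & use$type %in% c("DEL", "INS", "DUP")] %% 3L != 0L,
           "frameshift", "inframe")
  coding[in_cds & use$type %in% c("INV", "TRA")] <- "structural"

  ann <- data.frame(id = use$id, context = context, in_repeat = in_repeat,
                    coding_effect = coding, stringsAsFactors = FALSE)
  ctx_levels <- c("cds", "genic_noncds", "flank2kb", "intergenic")
  frac <- as.numeric(table(factor(context, ctx_levels))) / nrow(use)
  summary <- c(stats::setNames(frac, ctx_levels),
               frac_in_repeat = mean(in_repeat),
               frac_coding_change = mean(coding != "none"))
  list(annotations = ann, summary = summary, excluded = excluded)
}

#' Repeat-region enrichment of SVs
#'
#' SV midpoints (insertions: anchor points) are assigned to repeat or
#' nonrepeat sequence by point membership, and tested against the genomic
#' base-pair composition with a two-sided Fisher's exact test on the 2x2
#' table `[SVs-in-repeat, SVs-in-nonrepeat; repeat-bp, nonrepeat-bp]`
#' (two-sided p = sum over all tables with the observed margins whose
#' probability does not exceed the observed table's). Densities are reported
#' per `bin` bp of each compartment.
#'
#' @param nr an `nr_sv_set`.
#' @param repeats repeat data.frame (`chromosome`, `start`, `end`, `class`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin bp of compartment sequence per density unit (500 kb mirrors the
#'   landscape figure's intervals).
#' @return list with `table` (2x2 matrix), `density_repeat`,
#'   `density_nonrepeat` (SVs per `bin` bp), `odds_ratio` (sample OR) and
#'   `p_value`. Zero marginals give `p_value = NA` with a warning.
#' @export
repeat_enrichment <- function(nr, repeats, chrom_lengths, bin = 5e5) {
  stopifnot(inherits(nr, "nr_sv_set"))
  tab <- nr$table
  if (!all(tab$chromosome %in% names(chrom_lengths)))
    stop_input("chrom_lengths missing chromosomes present in the SV set")
  mask <- lapply(split(repeats, repeats$chromosome), function(df)
    IRanges::reduce(as_iranges0(df$start, df$end)))
  rep_bp <- sum(vapply(mask, function(ir) sum(IRanges::width(ir)), numeric(1)))
  total_bp <- sum(chrom_lengths)
  nonrep_bp <- total_bp - rep_bp

  mid <- ifelse(tab$type == "INS", tab$start, (tab$start + tab$end) %/% 2)
  in_rep <- logical(nrow(tab))
  for (chr in unique(tab$chromosome)) {
    sel <- tab$chromosome == chr
    if (!is.null(mask[[chr]]))
      in_rep[sel] <- IRanges::overlapsAny(point_iranges(mid[sel]), mask[[chr]])
  }
  sv_rep <- sum(in_rep)
  sv_nonrep <- sum(!in_rep)

  m <- matrix(c(sv_rep, sv_nonrep, rep_bp, nonrep_bp), nrow = 2L,
              byrow = TRUE,
              dimnames = list(c("sv_midpoints", "genome_bp"),
                              c("repeat", "nonrepeat")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero marginal in enrichment table; p undefined")
    p <- NA_real_
  } else {
    p <- stats::fisher.test(m)$p.value
  }
  list(table = m,
       density_repeat = if (rep_bp > 0) sv_rep / rep_bp * bin else NA_real_,
       density_nonrepeat = if (nonrep_bp > 0) sv_nonrep / nonrep_bp * bin
                           else NA_real_,
       odds_ratio = (sv_rep / sv_nonrep) / (rep_bp / nonrep_bp),
       p_value = p)
}

#' Partition a group's core SVs by inheritance from two ancestors
#'
#' "Core SVs" of the target group are the nonredundant records present in
#' every accession of the group. Each is attributed to ancestor A only,
#' ancestor B only, both, or neither, by presence in the respective ancestor
#' accessions (membership follows from the merge criterion that built the
#' nonredundant set).
#'
#' @param nr an `nr_sv_set`.
#' @param target character vector of target-group accessions.
#' @param ancestor_a,ancestor_b accession ids of the two candidate ancestors.
#' @return list with `counts` (named: onlyA, onlyB, both, neither), `total`
#'   and `core_ids`.
#' @export
ancestry_partition <- function(nr, target, ancestor_a, ancestor_b) {
  stopifnot(inherits(nr, "nr_sv_set"))
  pm <- nr$presence
  need <- c(target, ancestor_a, ancestor_b)
  if (!all(need %in% colnames(pm)))
    stop_input("accessions not in presence matrix: ",
               paste(setdiff(need, colnames(pm)), collapse = ", "))
  core <- rowSums(pm[, target, drop = FALSE]) == length(target)
  inA <- pm[, ancestor_a]
  inB <- pm[, ancestor_b]
  counts <- c(onlyA = sum(core & inA & !inB),
              onlyB = sum(core & !inA & inB),
              both = sum(core & inA & inB),
              neither = sum(core & !inA & !inB))
  list(counts = counts, total = sum(core),
       core_ids = nr$table$id[core])
}

#' Inversion hotspots
#'
#' Sliding windows (`window` bp wide, advancing by `step`) containing at
#' least `min_count` inversion midpoints are flagged; overlapping flagged
#' windows are merged into hotspot intervals.
#'
#' @param nr an `nr_sv_set`.
#' @param window window width in bp.
#' @param step slide step in bp.
#' @param min_count minimum inversion midpoints per window.
#' @return data.frame of hotspot intervals: `chromosome`, `start`, `end`,
#'   `n_inversions` (distinct inversions with midpoints inside the interval).
#' @export
inversion_hotspots <- function(nr, window = 1e6, step = 1e5, min_count = 3L) {
  stopifnot(inherits(nr, "nr_sv_set"))
  inv <- nr$table[nr$table$type == "INV", , drop = FALSE]
  out <- list()
  for (chr in unique(inv$chromosome)) {
    mid <- (inv$start[inv$chromosome == chr] +
            inv$end[inv$chromosome == chr]) %/% 2
    if (length(mid) < min_count) next
    starts <- seq(0, max(mid), by = step)
    cnt <- vapply(starts, function(s)
      sum(mid >= s & mid < s + window), numeric(1))
    hot <- starts[cnt >= min_count]
    if (length(hot) == 0L) next
    ir <- IRanges::reduce(as_iranges0(hot, hot + window))
    for (i in seq_along(ir)) {
      s <- IRanges::start(ir)[i] - 1L
      e <- IRanges::end(ir)[i]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, start = s, end = e,
        n_inversions = sum(mid >= s & mid < e),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_inversions = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (0 < alpha < 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples bonferroni_threshold(0.05, 9618384)
bonferroni_threshold <- function(alpha, n_tests) {
  if (!(alpha > 0 && alpha < 1)) stop_input("alpha must be in (0, 1)")
  if (n_tests < 1) stop_input("n_tests must be >= 1")
  alpha / n_tests
}
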