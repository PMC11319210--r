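# Synthetic SV landscape generator: five SV types with log-normal lengths,
# optional enrichment of midpoints in annotated repeat regions, and a
# two-ancestor inheritance structure over a target accession group.
#
# Every simulated SV is a "core" SV of the target group (carried by all its
# accessions) and is assigned an origin: inherited from ancestor A only, from
# ancestor B only, from both, or novel (absent from both ancestors). Default
# origin proportions follow the published partition 33 / 68 / 200 / 61 of
# 362; default type proportions follow the published five-category fractions.

.default_type_proportions <- c(DEL = 0.4699, INS = 0.5188, DUP = 0.0067,
                               INV = 0.0028, TRA = 0.0018)
.default_origin_proportions <- c(onlyA = 33, onlyB = 68, both = 200,
                                 novel = 61) / 362

# per-type log-normal length models (meanlog, sdlog), lengths offset past
# the 20 bp floor
.sv_length_models <- list(DEL = c(5.5, 1.0), INS = c(5.5, 1.0),
                          DUP = c(7.5, 0.8), INV = c(8.5, 0.8),
                          TRA = c(7.0, 0.8))

#' Simulate per-accession SV call sets with known origins
#'
#' @param accessions character vector of all accessions in the design (must
#'   contain the target group and both ancestors).
#' @param ancestry_design list with `target` (character vector),
#'   `ancestor_a`, `ancestor_b` (single accession ids) and optional
#'   `origin_proportions` (numeric over onlyA, onlyB, both, novel).
#' @param n_svs number of distinct (nonredundant) SVs to simulate.
#' @param type_proportions numeric over DEL, INS, DUP, INV, TRA, summing
#'   to 1.
#' @param repeat_enrichment_factor odds multiplier for SV midpoints falling
#'   in annotated repeat regions (1 = uniform placement).
#' @param annotation_bundle a bundle with `assembly` (named sequences or a
#'   named numeric vector of chromosome lengths) and `repeats`; repeats are
#'   required whenever the enrichment factor differs from 1.
#' @param seed integer seed.
#' @return list with `records` (per-accession SV data.frame in the
#'   [read_sv_table()] layout) and `manifest` (list: `seed`, `true_sv_origin`
#'   named by true SV index, `true_positions`, `generator_params`).
#' @export
simulate_sv_landscape <- function(accessions, ancestry_design,
                                  n_svs = 2000L,
                                  type_proportions = .default_type_proportions,
                                  repeat_enrichment_factor = 1,
                                  annotation_bundle, seed = 1L) {
  tp <- check_probabilities(type_proportions, .sv_types)
  op <- ancestry_design$origin_proportions
  if (is.null(op)) op <- .default_origin_proportions
  op <- check_probabilities(op, c("onlyA", "onlyB", "both", "novel"))
  target <- ancestry_design$target
  anc_a <- ancestry_design$ancestor_a
  anc_b <- ancestry_design$ancestor_b
  if (!all(c(target, anc_a, anc_b) %in% accessions))
    stop_input("target/ancestor accessions must appear in `accessions`")

  lens <- annotation_bundle$assembly
  if (is.character(lens)) lens <- vapply(lens, nchar, numeric(1))
  repeats <- annotation_bundle$repeats
  if (repeat_enrichment_factor != 1 &&
      (is.null(repeats) || nrow(repeats) == 0L))
    stop_input("repeat annotations required when enrichment factor != 1")
  set.seed(seed)

  types <- sample(.sv_types, n_svs, replace = TRUE, prob = tp)
  svlen <- integer(n_svs)
  for (tt in .sv_types) {
    sel <- types == tt
    mdl <- .sv_length_models[[tt]]
    svlen[sel] <- 20L + as.integer(ceiling(rlnorm(sum(sel), mdl[1], mdl[2])))
  }

  mids <- .place_midpoints(n_svs, lens, repeats, repeat_enrichment_factor)
  chrom <- mids$chromosome
  mid <- mids$position

  half <- svlen %/% 2L
  start <- pmax(0L, pmin(mid - half, as.integer(lens[chrom]) - svlen))
  end <- start + svlen
  is_ins <- types == "INS"
  start[is_ins] <- mid[is_ins]
  end[is_ins] <- mid[is_ins]

  origin <- sample(names(op), n_svs, replace = TRUE, prob = op)
  sv_id <- sprintf("truesv%05d", seq_len(n_svs))

  carriers <- lapply(seq_len(n_svs), function(i) {
    c(target,
      if (origin[i] %in% c("onlyA", "both")) anc_a,
      if (origin[i] %in% c("onlyB", "both")) anc_b)
  })
  n_rec <- lengths(carriers)
  records <- data.frame(
    accession = unlist(carriers),
    chromosome = rep(chrom, n_rec),
    start = rep(start, n_rec),
    end = rep(end, n_rec),
    type = rep(types, n_rec),
    length = rep(svlen, n_rec),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL

  list(records = records,
       manifest = list(
         seed = seed,
         true_sv_origin = stats::setNames(origin, sv_id),
         true_positions = data.frame(id = sv_id, chromosome = chrom,
                                     start = start, end = end, type = types,
                                     length = svlen,
                                     stringsAsFactors = FALSE),
         generator_params = list(n_svs = n_svs,
                                 type_proportions = as.list(tp),
                                 origin_proportions = as.list(op),
                                 repeat_enrichment_factor =
                                   repeat_enrichment_factor)))
}

# draw SV midpoints; repeat-membership odds are multiplied by `factor`
.place_midpoints <- function(n, lens, repeats, factor) {
  total <- sum(lens)
  if (is.null(repeats) || nrow(repeats) == 0L) {
    pos <- floor(runif(n, 0, total))
    return(.offset_to_chrom(pos, lens))
  }
  # repeat / nonrepeat compartment bookkeeping per chromosome
  masks <- lapply(names(lens), function(chr) {
    df <- repeats[repeats$chromosome == chr, , drop = FALSE]
    if (nrow(df) == 0L) IRanges::IRanges()
    else IRanges::reduce(as_iranges0(df$start, df$end))
  })
  names(masks) <- names(lens)
  rep_bp <- vapply(masks, function(ir) sum(IRanges::width(ir)), numeric(1))
  R <- sum(rep_bp)
  NR <- total - R
  p_rep <- factor * R / (factor * R + NR)
  in_rep <- runif(n) < p_rep
  pos_chr <- character(n)
  pos <- integer(n)
  # uniform offsets inside each compartment, mapped back to coordinates
  if (any(in_rep)) {
    off <- floor(runif(sum(in_rep), 0, R))
    hit <- .offset_in_mask(off, masks, rep_bp, lens, inside = TRUE)
    pos_chr[in_rep] <- hit$chromosome
    pos[in_rep] <- hit$position
  }
  if (any(!in_rep)) {
    off <- floor(runif(sum(!in_rep), 0, NR))
    hit <- .offset_in_mask(off, masks, lens - rep_bp, lens, inside = FALSE)
    pos_chr[!in_rep] <- hit$chromosome
    pos[!in_rep] <- hit$position
  }
  list(chromosome = pos_chr, position = pos)
}

.offset_to_chrom <- function(pos, lens) {
  cum <- cumsum(as.numeric(lens))
  idx <- findInterval(pos, c(0, cum), rightmost.closed = FALSE)
  list(chromosome = names(lens)[idx],
       position = as.integer(pos - c(0, cum)[idx]))
}

# map compartment offsets (0-based, cumulative over chromosomes) to genomic
# positions inside (or outside) the repeat masks
.offset_in_mask <- function(off, masks, comp_bp, lens, inside) {
  cum <- cumsum(as.numeric(comp_bp))
  idx <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
  chrs <- names(comp_bp)[idx]
  local_off <- off - c(0, cum)[idx]
  pos <- integer(length(off))
  for (chr in unique(chrs)) {
    sel <- chrs == chr
    ir <- masks[[chr]]
    segs <- if (inside) ir
            else IRanges::gaps(ir, start = 1L, end = as.integer(lens[chr]))
    w <- IRanges::width(segs)
    scum <- cumsum(as.numeric(w))
    si <- findInterval(local_off[sel], c(0, scum), rightmost.closed = FALSE)
    pos[sel] <- IRanges::start(segs)[si] - 1L +
      as.integer(local_off[sel] - c(0, scum)[si])
  }
  list(chromosome = chrs, position = pos)
}
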