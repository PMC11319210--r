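# Distance-based phylogenetics: classical Saitou-Nei neighbor joining with a
# deterministic lexicographic tie-break, plus the normalized edit distance
# used to compare centromeric monomers.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomerative NJ: at each step the pair minimizing
#' `Q(i,j) = (m - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' ties broken by the lexicographic order of the (smallest) leaf labels under
#' each node. Negative branch-length estimates are clamped to zero and
#' flagged via the `"clamped"` attribute. For additive distances the tree
#' reproduces the input path lengths exactly.
#'
#' @param dm symmetric numeric matrix (>= 3 labelled taxa) with zero
#'   diagonal; triangle-inequality violations are permitted.
#' @return an unrooted [ape::phylo] tree with branch lengths; attribute
#'   `"clamped"` is TRUE when any negative estimate was clamped.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop_input("neighbor joining needs >= 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs) || anyDuplicated(labs))
    stop_input("distance matrix needs unique row labels")
  if (max(abs(dm - t(dm))) > 1e-12 * max(1, max(abs(dm))))
    stop_input("distance matrix is not symmetric")
  if (any(dm < 0)) stop_input("negative distances")

  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)

  d <- dm
  frag <- labs           # Newick fragment per active node
  rep_lab <- labs        # lexicographic representative per active node

  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(q - qmin <= tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the sorted representative-label pair
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }

  # closed form for the final three nodes
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- paste0("(", frag[1], ":", fmt(la), ",",
                   frag[2], ":", fmt(lb), ",",
                   frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

#' Normalized edit distance between two sequences
#'
#' `Levenshtein(a, b) / max(|a|, |b|)`, in `[0, 1]`. Used as the monomer
#' comparison metric for clustering and monomer trees.
#'
#' @param a,b non-empty character strings.
#' @return numeric in `[0, 1]`.
#' @export
monomer_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}
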