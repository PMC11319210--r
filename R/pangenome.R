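# Pangenome composition and closure analysis.
#
# Gene families are classified from the PAV matrix into core / softcore /
# dispensable / private. Classification precedence is
#   core > softcore > private > dispensable:
# a family present in exactly one accession is both "missing in more than two"
# and "exclusive to one"; exclusivity wins so that a four-way partition with a
# private class is produced. At species level (presence = present in at least
# one member of the species) only three classes exist: core, dispensable and
# private — there is no species-level softcore.

.pan_classes <- c("core", "softcore", "dispensable", "private")

#' Classify gene families into pangenome classes
#'
#' Accession level: present in all accessions -> core; absent in exactly 1 or
#' 2 -> softcore; present in exactly 1 -> private; otherwise dispensable.
#' Species level (a family is "present in a species" when at least one member
#' accession carries it): present in all species -> core; exactly 1 species ->
#' private; otherwise dispensable.
#'
#' @param pav a [pav_matrix()] object.
#' @param level `"accession"` or `"species"`.
#' @return an object of class `pan_classification`: list with `level`,
#'   `label_of` (named character vector over families) and `composition`
#'   (data.frame with class, count, fraction).
#' @export
classify_families <- function(pav, level = c("accession", "species")) {
  stopifnot(inherits(pav, "pav_matrix"))
  level <- match.arg(level)
  m <- pav$presence
  if (nrow(m) == 0L) stop_input("empty PAV matrix")

  if (level == "accession") {
    n <- ncol(m)
    if (n < 4L) stop_input("accession-level classification needs >= 4 accessions")
    k <- rowSums(m)
    lab <- ifelse(k == n, "core",
           ifelse(k >= n - 2L, "softcore",
           ifelse(k == 1L, "private", "dispensable")))
    classes <- .pan_classes
  } else {
    sp <- unique(unname(pav$species))
    if (length(sp) < 3L) stop_input("species-level classification needs >= 3 species")
    sp_pres <- vapply(sp, function(s)
      rowSums(m[, pav$species == s, drop = FALSE]) > 0L,
      logical(nrow(m)))
    if (nrow(m) == 1L) sp_pres <- matrix(sp_pres, nrow = 1L)
    k <- rowSums(sp_pres)
    lab <- ifelse(k == length(sp), "core",
           ifelse(k == 1L, "private", "dispensable"))
    classes <- setdiff(.pan_classes, "softcore")
  }
  lab <- stats::setNames(lab, rownames(m))
  counts <- vapply(classes, function(cl) sum(lab == cl), numeric(1))
  comp <- data.frame(class = classes, count = as.integer(counts),
                     fraction = counts / length(lab),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(level = level, label_of = lab, composition = comp),
            class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  cat("Pangenome classification (", x$level, " level):\n", sep = "")
  print(transform(x$composition, pct = sprintf("%.2f%%", 100 * fraction)),
        row.names = FALSE)
  invisible(x)
}

#' Pangenome / core-genome saturation curves
#'
#' For each replicate a uniform random permutation of accessions is drawn
#' (sampling without replacement). The pangenome size at n is the number of
#' families present in at least one of the first n accessions; the
#' core-genome size is the number present in all of them.
#'
#' @param pav a [pav_matrix()] object.
#' @param replicates number of random orderings (field practice uses 100).
#' @param seed optional integer seed.
#' @return object of class `saturation_curve`: list with `n` (1..N), `pan`
#'   and `core` (N x replicates integer matrices) and `replicates`.
#' @export
saturation_curves <- function(pav, replicates = 100L, seed = NULL) {
  stopifnot(inherits(pav, "pav_matrix"))
  if (replicates < 1L) stop_input("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- pav$presence
  n_acc <- ncol(m)
  pan <- core <- matrix(0L, nrow = n_acc, ncol = replicates)
  all_present <- rowSums(m) == n_acc
  for (r in seq_len(replicates)) {
    perm <- sample.int(n_acc)
    a <- m[, perm, drop = FALSE]
    # index of first accession carrying the family (rows are never all-zero)
    first_in <- max.col(a, ties.method = "first")
    # index of first accession missing the family; N+1 when present everywhere
    first_out <- max.col(!a, ties.method = "first")
    first_out[all_present] <- n_acc + 1L
    pan[, r] <- cumsum(tabulate(first_in, nbins = n_acc))
    core[, r] <- nrow(m) - cumsum(tabulate(first_out, nbins = n_acc))
  }
  structure(list(n = seq_len(n_acc), pan = pan, core = core,
                 replicates = replicates),
            class = "saturation_curve")
}

#' Fit a Heaps-law closure model to a saturation curve
#'
#' The mean number of new families contributed by the n-th genome,
#' `delta(n) = mean(pan(n) - pan(n-1))`, is fitted as `kappa * n^(-alpha)` by
#' least squares on the log-transformed means over n = 2..N. Zero means are
#' dropped; fewer than 3 usable points is an error. The pangenome is declared
#' closed when `alpha > 1` (a decay fast enough that the pan-size series
#' converges). A curve with no growth at all gets `alpha = Inf`.
#'
#' @param curve a [saturation_curves()] result with N >= 4.
#' @return object of class `closure_fit`: list with `alpha`, `kappa`,
#'   `fit_error` (residual sum of squares on the log scale), `n_points` and
#'   `verdict` ("open" or "closed").
#' @export
fit_closure <- function(curve) {
  stopifnot(inherits(curve, "saturation_curve"))
  N <- length(curve$n)
  if (N < 4L) stop_input("closure fitting needs at least 4 accessions")
  delta <- rowMeans(curve$pan[-1L, , drop = FALSE] -
                    curve$pan[-N, , drop = FALSE])
  n <- 2:N
  if (all(delta == 0)) {
    return(structure(list(alpha = Inf, kappa = 0, fit_error = 0,
                          n_points = 0L, verdict = "closed"),
                     class = "closure_fit"))
  }
  keep <- delta > 0
  if (sum(keep) < 3L) stop_input("fewer than 3 usable points for closure fit")
  fit <- stats::lm(log(delta[keep]) ~ log(n[keep]))
  alpha <- -unname(coef(fit)[2])
  structure(list(alpha = alpha,
                 kappa = exp(unname(coef(fit)[1])),
                 fit_error = sum(stats::residuals(fit)^2),
                 n_points = sum(keep),
                 verdict = if (alpha > 1) "closed" else "open"),
            class = "closure_fit")
}

#' @export
print.closure_fit <- function(x, ...) {
  cat(sprintf("Heaps-law closure fit: alpha = %.3f (%s pangenome)\n",
              x$alpha, x$verdict))
  invisible(x)
}

#' Nucleotide diversity (pi) of an aligned sequence set
#'
#' `pi = 2 / (n (n - 1)) * sum_{i<j} d_ij / L_ij`, where `d_ij` counts
#' mismatching aligned positions and positions carrying a gap (`-`) or `N` in
#' either sequence are excluded from both `d_ij` and that pair's effective
#' length `L_ij`.
#'
#' @param alignment character vector of >= 2 equal-length aligned sequences.
#' @return a single numeric value; pairs with zero effective length make the
#'   result `NA` with a warning.
#' @export
nucleotide_diversity <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop_input("need at least 2 sequences")
  L <- unique(nchar(alignment))
  if (length(L) != 1L || L == 0L)
    stop_input("sequences must be aligned (equal, positive length)")
  chars <- lapply(toupper(alignment), function(s) strsplit(s, "")[[1]])
  ok <- lapply(chars, function(v) v != "-" & v != "N")
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[[i]] & ok[[j]]
      Lij <- sum(use)
      if (Lij == 0L) {
        warning("pair with zero effective alignment length; pi undefined")
        return(NA_real_)
      }
      total <- total + sum(chars[[i]][use] != chars[[j]][use]) / Lij
    }
  }
  2 * total / (n * (n - 1))
}

#' Jaccard PAV distance between accessions
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on the accessions' family
#' presence sets.
#'
#' @param pav a [pav_matrix()] object with >= 2 accessions.
#' @return symmetric numeric matrix with zero diagonal, labelled by accession.
#' @export
pav_distance <- function(pav) {
  stopifnot(inherits(pav, "pav_matrix"))
  m <- pav$presence * 1L
  if (ncol(m) < 2L) stop_input("need at least 2 accessions")
  if (any(colSums(m) == 0L))
    stop_input("accession with empty family set: distance undefined")
  inter <- crossprod(m)                 # |A n B|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}
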