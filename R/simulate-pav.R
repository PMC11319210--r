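# Synthetic PAV matrix generator with ground-truth manifest.
#
# Class constructions (chosen so that the four classes are exactly separable
# by the classifier's definitions):
#   core        : present in all accessions;
#   softcore    : absent in 1 or 2 accessions (count and identities uniform);
#   dispensable : present in k accessions with 2 <= k <= N - 3, k drawn from
#                 a truncated geometric (decay `dispensable_decay`), giving
#                 the low-occupancy arm of the U-shaped occupancy spectrum;
#   private     : present in exactly one accession (uniform).

#' Default accession panel: 28 accessions across 7 species groups
#'
#' Mirrors the composition of a genus-wide watermelon panel (14 C. lanatus
#' including the reference, 2 C. mucosospermus, 5 C. amarus,
#' 4 C. colocynthis, 1 each of C. rehmii, C. ecirrhosus, C. naudinianus).
#'
#' @return named character vector accession -> species group.
#' @export
default_species_map <- function() {
  counts <- c(lanatus = 14L, mucosospermus = 2L, amarus = 5L,
              colocynthis = 4L, rehmii = 1L, ecirrhosus = 1L,
              naudinianus = 1L)
  sp <- rep(names(counts), counts)
  stats::setNames(sp, sprintf("%s_%02d", sp, unlist(lapply(counts, seq_len))))
}

#' Simulate a PAV matrix with known family classes
#'
#' @param n_accessions number of accessions (>= 4).
#' @param species_map named character vector accession -> species; defaults
#'   to [default_species_map()] (must have `n_accessions` entries).
#' @param n_families number of gene families.
#' @param class_proportions numeric length-4 over
#'   (core, softcore, dispensable, private), summing to 1; defaults to the
#'   published per-genome class percentages 42.78 / 8.80 / 45.87 / 2.55.
#' @param dispensable_decay geometric decay rate for dispensable occupancy.
#' @param seed integer seed.
#' @return list with `pav` (a [pav_matrix()]) and `manifest` (list: `seed`,
#'   `true_family_classes`, `generator_params`).
#' @export
simulate_pav <- function(n_accessions = 28L, species_map = NULL,
                         n_families = 20000L,
                         class_proportions = c(core = 0.4278,
                                               softcore = 0.0880,
                                               dispensable = 0.4587,
                                               private = 0.0255),
                         dispensable_decay = 0.3, seed = 1L) {
  if (n_accessions < 4L)
    stop_input("need >= 4 accessions for well-defined classes")
  p <- check_probabilities(class_proportions, .pan_classes)
  if (is.null(species_map)) {
    species_map <- default_species_map()
    if (n_accessions != length(species_map))
      species_map <- stats::setNames(
        rep(unique(species_map), length.out = n_accessions),
        sprintf("acc_%02d", seq_len(n_accessions)))
  }
  if (length(species_map) != n_accessions)
    stop_input("species_map must cover exactly n_accessions accessions")
  set.seed(seed)

  acc <- names(species_map)
  cls <- sample(.pan_classes, n_families, replace = TRUE, prob = p)
  m <- matrix(FALSE, nrow = n_families, ncol = n_accessions,
              dimnames = list(sprintf("fam%05d", seq_len(n_families)), acc))

  m[cls == "core", ] <- TRUE

  idx_soft <- which(cls == "softcore")
  for (i in idx_soft) {
    n_absent <- sample(1:2, 1L)
    m[i, ] <- TRUE
    m[i, sample.int(n_accessions, n_absent)] <- FALSE
  }

  idx_disp <- which(cls == "dispensable")
  if (length(idx_disp)) {
    kmax <- n_accessions - 3L
    support <- 2:kmax
    pk <- (1 - dispensable_decay)^(support - 2L)
    ks <- sample(support, length(idx_disp), replace = TRUE, prob = pk)
    for (jj in seq_along(idx_disp))
      m[idx_disp[jj], sample.int(n_accessions, ks[jj])] <- TRUE
  }

  idx_priv <- which(cls == "private")
  if (length(idx_priv))
    m[cbind(idx_priv, sample.int(n_accessions, length(idx_priv),
                                 replace = TRUE))] <- TRUE

  list(pav = pav_matrix(m, species_map),
       manifest = list(
         seed = seed,
         true_family_classes = stats::setNames(cls, rownames(m)),
         generator_params = list(n_accessions = n_accessions,
                                 n_families = n_families,
                                 class_proportions = as.list(p),
                                 dispensable_decay = dispensable_decay)))
}
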