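# PAV (presence-absence variation) matrix container and TSV I/O.
#
# The PAV matrix is the substrate of the whole pangenome pipeline: a logical
# families x accessions matrix plus a map accession -> species group.

#' Construct a PAV matrix object
#'
#' @param presence logical (or 0/1) matrix, families in rows, accessions in
#'   columns; dimnames required. All-zero family rows are rejected.
#' @param species named character vector mapping every accession to a species
#'   group.
#' @return an object of class `pav_matrix` with elements `presence` (logical
#'   matrix) and `species` (named character vector).
#' @export
pav_matrix <- function(presence, species) {
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop_input("presence matrix needs family rownames and accession colnames")
  if (!is.logical(presence)) {
    if (!all(presence %in% c(0, 1)))
      stop_input("presence cells must be 0/1")
    presence <- presence == 1
  }
  if (anyDuplicated(colnames(presence)))
    stop_input("duplicate accession ids")
  if (anyDuplicated(rownames(presence)))
    stop_input("duplicate family ids")
  if (any(rowSums(presence) == 0L))
    stop_input("all-zero family rows are not allowed in a PAV matrix")
  acc <- colnames(presence)
  if (!all(acc %in% names(species)))
    stop_input("species map missing accessions: ",
               paste(setdiff(acc, names(species)), collapse = ", "))
  structure(list(presence = presence, species = species[acc]),
            class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat("PAV matrix:", nrow(x$presence), "families x",
      ncol(x$presence), "accessions,",
      length(unique(x$species)), "species groups\n")
  invisible(x)
}

#' Read a PAV matrix from TSV
#'
#' Expected layout: first column `family`, remaining columns one per
#' accession, cells strictly 0/1. The species map comes either from
#' `species` (named vector) or from a two-column TSV (`accession`, `species`).
#'
#' @param path PAV TSV path.
#' @param species named character vector, or path to a species-map TSV.
#' @return a [pav_matrix()] object.
#' @export
read_pav_matrix <- function(path, species) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "family")
    stop_input("PAV TSV must start with a 'family' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0L, 1L)))
    stop_input("PAV cells must be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- df$family
  if (is.character(species) && length(species) == 1L && file.exists(species)) {
    sm <- read.table(species, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    species <- stats::setNames(sm$species, sm$accession)
  }
  pav_matrix(m, species)
}

#' Write a PAV matrix to TSV (plus optional species map)
#'
#' @param pav a [pav_matrix()] object.
#' @param path output TSV path.
#' @param species_path optional path for the accession->species map TSV.
#' @return `path`, invisibly.
#' @export
write_pav_matrix <- function(pav, path, species_path = NULL) {
  stopifnot(inherits(pav, "pav_matrix"))
  df <- data.frame(family = rownames(pav$presence),
                   pav$presence * 1L, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(species_path))
    write.table(data.frame(accession = names(pav$species),
                           species = unname(pav$species)),
                species_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
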