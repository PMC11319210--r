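# Newick round-tripping, delegated to ape. Branch lengths survive to at
# least 6 significant digits.

#' Write a phylogenetic tree to Newick
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a phylogenetic tree from Newick
#' @param path input path.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
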