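# FASTA I/O on top of Biostrings, with the validation contract the rest of
# the toolkit assumes (unique ids, non-empty records, IUPAC alphabet only).

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased. Duplicate record ids, empty records and
#' non-IUPAC characters are rejected rather than coerced.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop_input("duplicate FASTA ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    stop_input("empty FASTA record(s): ",
               paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  seqs <- toupper(as.character(set))
  alpha <- paste(setdiff(Biostrings::DNA_ALPHABET, "-"), collapse = "")
  bad <- grepl(paste0("[^", alpha, "-]"), seqs)
  if (any(bad))
    stop_input("non-IUPAC characters in record(s): ",
               paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
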