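# Gene models (GFF3) and repeat annotations (BED), imported via rtracklayer
# and converted to the package's 0-based half-open convention.

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features into a list of gene models. GFF3 coordinates
#' (1-based closed) are converted to 0-based half-open. When a gene has
#' several mRNAs the first by position is used. CDS parts are stored sorted
#' 5'->3' on the feature strand.
#'
#' @param path path to a GFF3 file.
#' @return a list of gene models; each is a list with elements `id`,
#'   `chromosome`, `start`, `end` (0-based half-open), `strand` and
#'   `cds_parts` (two-column matrix `start`,`end`, possibly zero rows).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(list())
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) return(list())
  mrnas <- gr[type == "mRNA"]
  cds <- gr[type == "CDS"]
  cds_parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- g$ID
    # CDS may be attached to an mRNA child or to the gene directly
    my_mrna <- mrnas[vapply(as.list(mrnas$Parent), function(p)
      length(p) > 0 && p[[1]] == gid, logical(1))]
    if (length(my_mrna) > 0L) {
      my_mrna <- my_mrna[order(GenomicRanges::start(my_mrna))][1]
      my_cds <- cds[!is.na(cds_parent) & cds_parent == my_mrna$ID]
    } else {
      my_cds <- cds[!is.na(cds_parent) & cds_parent == gid]
    }
    gstart <- GenomicRanges::start(g) - 1L
    gend <- GenomicRanges::end(g)
    parts <- cbind(start = GenomicRanges::start(my_cds) - 1L,
                   end = GenomicRanges::end(my_cds))
    if (nrow(parts) > 0L) {
      if (any(parts[, "start"] < gstart) || any(parts[, "end"] > gend))
        stop_input("CDS outside parent span for gene ", gid)
      strand <- as.character(GenomicRanges::strand(g))
      ord <- order(parts[, "start"], decreasing = identical(strand, "-"))
      parts <- parts[ord, , drop = FALSE]
    }
    out[[i]] <- list(
      id = gid,
      chromosome = as.character(GenomicRanges::seqnames(g)),
      start = gstart, end = gend,
      strand = as.character(GenomicRanges::strand(g)),
      cds_parts = parts
    )
  }
  out
}

#' Read repeat annotations from BED
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' The BED name column carries the repeat class label (e.g. "LTR/Gypsy").
#'
#' @param path path to a BED file with at least 4 columns.
#' @return a data.frame with columns `chromosome`, `start`, `end`, `class`.
#' @export
read_repeat_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- gr$name
  if (is.null(cls) || any(is.na(cls)) || any(!nzchar(cls)))
    stop_input("repeat BED requires a non-empty class label in the name column")
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    class = as.character(cls),
    stringsAsFactors = FALSE
  )
}

#' Write repeat annotations to BED
#' @param repeats data.frame as returned by [read_repeat_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  df <- repeats[, c("chromosome", "start", "end", "class")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()] for the fields the toolkit uses (gene + CDS).
#'
#' @param genes list of gene models (see [read_gff3()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(paste(g$chromosome, "panmelon", "gene", g$start + 1L, g$end,
                     ".", g$strand, ".", paste0("ID=", g$id), sep = "\t"), con)
    mid <- paste0(g$id, ".t1")
    writeLines(paste(g$chromosome, "panmelon", "mRNA", g$start + 1L, g$end,
                     ".", g$strand, ".",
                     paste0("ID=", mid, ";Parent=", g$id), sep = "\t"), con)
    if (nrow(g$cds_parts) > 0L) {
      for (j in seq_len(nrow(g$cds_parts))) {
        writeLines(paste(g$chromosome, "panmelon", "CDS",
                         g$cds_parts[j, "start"] + 1L, g$cds_parts[j, "end"],
                         ".", g$strand, "0",
                         paste0("ID=", mid, ".cds;Parent=", mid), sep = "\t"),
                   con)
      }
    }
  }
  invisible(path)
}
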