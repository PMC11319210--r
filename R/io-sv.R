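# Structural-variant call-set I/O. Two dialects:
#  * VCF 4.x with symbolic ALT alleles (<DEL>, <INS>, <DUP>, <INV>, <TRA>/<BND>),
#    INFO END and SVLEN, read via VariantAnnotation;
#  * the project TSV exchange format, a header line
#      accession chromosome start end type length
#    with 0-based half-open coordinates (insertions: start == end and length =
#    inserted-sequence length).
# Records at or below `min_len` bp are excluded with a logged count, matching
# the >20 bp floor used throughout the SV landscape analysis.

.sv_types <- c("DEL", "INS", "DUP", "INV", "TRA")

.sv_type_map <- c(
  DEL = "DEL", DELETION = "DEL",
  INS = "INS", INSERTION = "INS",
  DUP = "DUP", DUPLICATION = "DUP",
  INV = "INV", INVERSION = "INV",
  TRA = "TRA", TRANSLOCATION = "TRA", BND = "TRA"
)

map_sv_type <- function(x) {
  out <- .sv_type_map[toupper(x)]
  if (any(is.na(out)))
    stop_input("unknown SV type code(s): ",
               paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a structural-variant call set
#'
#' @param path path to a VCF (symbolic SV alleles) or project-TSV file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param accession accession id for the call set; for VCF, defaults to the
#'   single sample name when present.
#' @param min_len minimum SV length in bp (exclusive floor is `min_len - 1`);
#'   default keeps SVs > 20 bp. Shorter records are dropped and their number
#'   reported via a message and the `"n_filtered"` attribute.
#' @return data.frame with columns `accession`, `chromosome`, `start`, `end`
#'   (0-based half-open; `start == end` for insertions), `type` (one of
#'   DEL/INS/DUP/INV/TRA) and `length` (bp).
#' @export
read_sv_table <- function(path, dialect = c("tsv", "vcf"), accession = NULL,
                          min_len = 21L) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "tsv") .read_sv_tsv(path, accession)
        else .read_sv_vcf(path, accession)
  if (any(df$length < 0)) stop_input("negative SV length")
  keep <- df$length >= min_len
  n_filtered <- sum(!keep)
  if (n_filtered > 0L)
    message("read_sv_table: excluded ", n_filtered,
            " record(s) shorter than ", min_len, " bp")
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_filtered") <- n_filtered
  df
}

.read_sv_tsv <- function(path, accession) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "type", "length")
  if (!all(need %in% names(df)))
    stop_input("SV TSV must carry columns: accession (optional), ",
               paste(need, collapse = ", "))
  if (!"accession" %in% names(df)) {
    if (is.null(accession)) stop_input("no accession column and none supplied")
    df$accession <- accession
  }
  df$type <- map_sv_type(df$type)
  ins <- df$type == "INS"
  if (any(df$end[!ins] <= df$start[!ins]))
    stop_input("non-insertion SV with end <= start")
  df$end[ins] <- df$start[ins]
  df[, c("accession", "chromosome", "start", "end", "type", "length")]
}

.read_sv_vcf <- function(path, accession) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- length(vcf)
  if (n == 0L)
    return(data.frame(accession = character(), chromosome = character(),
                      start = integer(), end = integer(), type = character(),
                      length = integer(), stringsAsFactors = FALSE))
  if (is.null(accession)) {
    smp <- colnames(vcf)
    if (length(smp) == 1L) accession <- smp
    else stop_input("supply `accession` for VCFs without a single sample")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  info <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE)
            else gsub("[<>]", "", alt)
  type <- map_sv_type(svtype)
  pos <- GenomicRanges::start(rr)           # 1-based POS (base before event)
  end1 <- if ("END" %in% names(info)) as.integer(unlist(info$END))
          else GenomicRanges::end(rr)
  svlen <- if ("SVLEN" %in% names(info))
    abs(as.integer(vapply(as.list(info$SVLEN),
                          function(v) if (length(v)) v[[1]] else NA_integer_,
                          integer(1))))
    else rep(NA_integer_, n)
  start0 <- pos                              # POS is the base before: [POS, END]
  end0 <- ifelse(type == "INS", pos, end1)
  len <- ifelse(type == "INS", svlen, end0 - start0)
  len[is.na(len)] <- (end0 - start0)[is.na(len)]
  data.frame(accession = accession,
             chromosome = as.character(GenomicRanges::seqnames(rr)),
             start = as.integer(start0), end = as.integer(end0),
             type = type, length = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Write a structural-variant call set in the project TSV dialect
#' @param svs data.frame as returned by [read_sv_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(svs, path) {
  write.table(svs[, c("accession", "chromosome", "start", "end",
                      "type", "length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
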