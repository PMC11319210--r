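# Shared helpers: coordinate conventions, sequence utilities, input checks.
#
# Convention: all intervals handled inside the package are 0-based half-open
# [start, end). GFF3 (1-based closed) and VCF POS (1-based) are converted at
# the reader boundary; IRanges objects are built on demand for overlap work.

#' Convert a 0-based half-open interval to an IRanges
#'
#' Zero-width intervals (insertion anchors) become zero-width IRanges; use
#' [point_iranges()] when point-overlap semantics are wanted instead.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return an [IRanges::IRanges] object (1-based closed, as IRanges requires).
#' @keywords internal
#' @noRd
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# 0-based point position -> 1-bp IRanges covering the base to its right,
# so that point p "is in" [a, b) iff the ranges overlap.
point_iranges <- function(pos) {
  IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L)
}

# 0-based half-open GRanges
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = as_iranges0(start, end))
}

#' Reverse complement of a DNA string
#' @param x a single character string over the DNA alphabet.
#' @return the reverse complement as a character string.
#' @export
#' @examples revcomp("CCCTAAA")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#' @param n length in bp.
#' @param gc GC content, default 0.36 (watermelon-like).
#' @return a character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.36) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# integer codes for fast base comparison; A,C,G,T -> 1..4, anything else 5+
seq_codes <- function(x) {
  code <- utf8ToInt(x)
  out <- integer(length(code))
  out[code == 65L] <- 1L  # A
  out[code == 67L] <- 2L  # C
  out[code == 71L] <- 3L  # G
  out[code == 84L] <- 4L  # T
  out[out == 0L] <- 5L + (code[out == 0L] %% 7L)
  out
}

# substitute bases at given 1-based positions with a uniformly drawn
# *different* base; cyclic-offset trick keeps it fully vectorized
mutate_positions <- function(x, pos) {
  if (length(pos) == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  idx <- match(ch[pos], bases)
  idx[is.na(idx)] <- 1L  # non-ACGT positions mutate from an arbitrary anchor
  off <- sample.int(3L, length(pos), replace = TRUE)
  ch[pos] <- bases[((idx - 1L + off) %% 4L) + 1L]
  paste(ch, collapse = "")
}

#' Mutate a sequence at a fixed per-base substitution rate
#'
#' Each position is substituted independently with probability `rate`; the
#' replacement base is drawn uniformly from the three alternatives.
#'
#' @param x a DNA string.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return the mutated string.
#' @export
mutate_sequence <- function(x, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- nchar(x)
  pos <- which(runif(n) < rate)
  mutate_positions(x, pos)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_probabilities <- function(p, classes, tol = 1e-9) {
  if (length(p) != length(classes))
    stop_input("expected ", length(classes), " proportions (",
               paste(classes, collapse = ", "), ")")
  if (any(p < 0)) stop_input("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop_input("proportions must sum to 1 (got ", format(sum(p)), ")")
  stats::setNames(as.numeric(p), classes)
}
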