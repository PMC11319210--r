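# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (enumeration, dynamic programming,
# transitive closure) and never call the implementation paths they check.

jaccard_span <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / ((a[2] - a[1]) + (b[2] - b[1]) - inter)
}

# full-traceback dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# exhaustive two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, sum probabilities <= the observed one
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  prob <- vapply(support, function(x)
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1), numeric(1))
  p_obs <- prob[support == m[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# all-pairs merge criterion + transitive closure by boolean matrix powering;
# returns a component id per record (records must share chromosome and type)
merge_components_oracle <- function(sub, ro = 0.5, win = 100, lr = 0.5) {
  n <- nrow(sub)
  M <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      type <- sub$type[i]
      hit <- if (type %in% c("DEL", "DUP", "INV")) {
        inter <- min(sub$end[i], sub$end[j]) - max(sub$start[i], sub$start[j])
        li <- sub$end[i] - sub$start[i]
        lj <- sub$end[j] - sub$start[j]
        inter >= ro * li && inter >= ro * lj
      } else if (type == "INS") {
        abs(sub$start[i] - sub$start[j]) <= win &&
          min(sub$length[i], sub$length[j]) /
          max(sub$length[i], sub$length[j]) >= lr
      } else {
        abs(sub$start[i] - sub$start[j]) <= win &&
          abs(sub$end[i] - sub$end[j]) <= win
      }
      M[i, j] <- M[i, j] || hit
    }
  }
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) break
    M <- M2
  }
  match(apply(M, 1, paste, collapse = ""),
        unique(apply(M, 1, paste, collapse = "")))
}

# smallest period in `range` whose shifted-self identity over the region
# meets the threshold; NA when none does
brute_period <- function(sequence, start0, end0, range = 5:200,
                         min_identity = 0.8) {
  x <- strsplit(sequence, "")[[1]]
  s <- start0 + 1L
  e <- end0
  for (p in range) {
    if (e - p < s) next
    if (mean(x[s:(e - p)] == x[(s + p):e]) >= min_identity) return(p)
  }
  NA_integer_
}

# four class definitions applied in fixed precedence, straight from their
# statements (accession level)
classify_oracle <- function(m) {
  n <- ncol(m)
  apply(m, 1, function(row) {
    k <- sum(row)
    if (k == n) "core"
    else if ((n - k) %in% c(1L, 2L)) "softcore"
    else if (k == 1L) "private"
    else "dispensable"
  })
}

# position-by-position pairwise pi oracle
pi_oracle <- function(alignment) {
  chars <- lapply(toupper(alignment), function(s) strsplit(s, "")[[1]])
  n <- length(chars)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      use <- chars[[i]] != "-" & chars[[i]] != "N" &
             chars[[j]] != "-" & chars[[j]] != "N"
      tot <- tot + sum(chars[[i]][use] != chars[[j]][use]) / sum(use)
    }
  }
  2 * tot / (n * (n - 1))
}

# deterministic random records for merge tests
random_sv_records <- function(n, seed, chroms = "chr1",
                              accessions = c("a1", "a2", "a3"),
                              span_max = 5e4) {
  set.seed(seed)
  type <- sample(c("DEL", "INS", "DUP", "INV", "TRA"), n, replace = TRUE,
                 prob = c(0.35, 0.35, 0.1, 0.1, 0.1))
  len <- 21L + as.integer(rlnorm(n, 4, 1))
  start <- as.integer(runif(n, 0, span_max))
  end <- ifelse(type == "INS", start, start + len)
  data.frame(accession = sample(accessions, n, replace = TRUE),
             chromosome = sample(chroms, n, replace = TRUE),
             start = start, end = end, type = type, length = len,
             stringsAsFactors = FALSE)
}

expect_same_partition <- function(nr, records, ...) {
  # component structure comparison per chromosome x type group
  for (chr in unique(records$chromosome)) {
    for (tt in unique(records$type)) {
      sub <- records[records$chromosome == chr & records$type == tt, ,
                     drop = FALSE]
      if (nrow(sub) == 0) next
      comp <- merge_components_oracle(sub, ...)
      got <- nr$table[nr$table$chromosome == chr & nr$table$type == tt, ,
                      drop = FALSE]
      expect_equal(nrow(got), length(unique(comp)))
      expect_equal(sort(got$n_members), sort(as.integer(table(comp))))
    }
  }
}
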