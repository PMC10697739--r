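# Independent oracles used across the suite. These deliberately avoid the
# package's compiled paths: per-character comparison for LCP, and exhaustive
# enumeration of alignment paths (branch-and-bound) for small gap-affine
# instances.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-character LCP oracle on plain strings, 0-based offsets.
naive_lcp <- function(a, b, i, j) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ka <- length(ca) - i
  kb <- length(cb) - j
  k <- min(ka, kb)
  if (k <= 0) return(0L)
  sa <- ca[i + seq_len(k)]
  sb <- cb[j + seq_len(k)]
  mism <- which(sa != sb)
  if (length(mism)) mism[1] - 1L else k
}

# Exhaustive enumeration of every alignment path, scored with affine gaps.
# Feasible for lengths <= ~7; the oracle-of-the-oracle for gotoh_align().
enum_affine_score <- function(q, t, p) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc)
  m <- length(tc)
  best <- Inf
  rec <- function(i, j, last, cost) {
    if (cost >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- cost
      return(invisible(NULL))
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, "M", cost + if (qc[i + 1] == tc[j + 1]) 0 else p$x)
    if (j < m)
      rec(i, j + 1, "I", cost + p$e + if (last == "I") 0 else p$o)
    if (i < n)
      rec(i + 1, j, "D", cost + p$e + if (last == "D") 0 else p$o)
    invisible(NULL)
  }
  rec(0L, 0L, "M", 0)
  best
}

# The penalty sets exercised throughout the randomized suites.
penalty_grid <- list(
  wfa_penalties(4, 6, 2),
  wfa_penalties(1, 0, 1),
  wfa_penalties(2, 3, 1),
  wfa_penalties(5, 2, 4)
)

# CIGAR must consume the two sequences exactly.
expect_cigar_consumes <- function(cigar, query, text) {
  cc <- cigar_consumed(cigar)
  expect_identical(unname(cc["query"]), nchar(query))
  expect_identical(unname(cc["text"]), nchar(text))
}
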