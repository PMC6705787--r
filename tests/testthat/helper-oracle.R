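# Independent alignment oracles: exhaustive enumeration of global
# alignments (no dynamic-programming shortcuts shared with the package
# implementation), a memoized variant for slightly longer inputs, and a
# classic longest-common-subsequence recurrence.

# Maximum score over all global alignments, linear gap cost per gap column.
# Pure recursion: every alignment path is enumerated.  Feasible for
# lengths <= ~6.
bf_score <- function(a, b, match = 1, mismatch = 0, gap = 0) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Same quantity, memoized on the (i, j) suffix so lengths ~10 are feasible.
bf_score_memo <- function(a, b, match = 1, mismatch = 0, gap = 0) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1))
    memo[i, j] <<- best
    best
  }
  rec(1, 1)
}

# Affine gaps: the first gap column of a run costs gap_open, later columns
# gap_extend.  State = which gap run (if any) the previous column belongs
# to.  Pure recursion, lengths <= ~5.
bf_score_affine <- function(a, b, match, mismatch, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, st) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (i <= n)
      best <- max(best, (if (st == 1L) gap_extend else gap_open) +
                    rec(i + 1, j, 1L))
    if (j <= m)
      best <- max(best, (if (st == 2L) gap_extend else gap_open) +
                    rec(i, j + 1, 2L))
    best
  }
  rec(1, 1, 0L)
}

# Longest common subsequence length by the textbook recurrence.
lcs_length <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  L <- matrix(0L, length(ca) + 1, length(cb) + 1)
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      L[i + 1, j + 1] <- if (ca[i] == cb[j]) L[i, j] + 1L
                         else max(L[i, j + 1], L[i + 1, j])
    }
  }
  L[length(ca) + 1, length(cb) + 1]
}

random_seq <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
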