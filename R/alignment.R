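#' Scoring scheme for global alignment
#'
#' The default mirrors the "standard parameters" of common global-alignment
#' routines for this kind of census: match = 1, mismatch = 0, and free gaps
#' (all gap penalties 0), i.e. a globally optimal match-count alignment.
#' A substitution table (e.g. BLOSUM62) with affine gap penalties can be
#' supplied for sensitivity analysis; with `gap_open == gap_extend` the gap
#' model is linear, otherwise the first gap residue costs `gap_open` and
#' each further residue `gap_extend`.
#'
#' @param match Score for identical residues.
#' @param mismatch Score for differing residues (also used for X against
#'   anything, including X).
#' @param gap_open Penalty (<= 0) of the first residue of a gap run.
#' @param gap_extend Penalty (<= 0) of each further gap residue.
#' @param substitution Optional symmetric numeric matrix with single-letter
#'   amino-acid dimnames, overriding `match`/`mismatch`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = 0, gap_open = 0,
                           gap_extend = 0, substitution = NULL) {
  if (gap_open > 0 || gap_extend > 0)
    s1_validation_error("gap penalties must be non-positive")
  if (!is.null(substitution)) {
    if (!is.matrix(substitution) || is.null(dimnames(substitution)))
      s1_validation_error("substitution must be a matrix with residue dimnames")
    common <- intersect(rownames(substitution), colnames(substitution))
    sq <- substitution[common, common, drop = FALSE]
    if (!isTRUE(all.equal(sq, t(sq))))
      s1_validation_error("substitution table must be symmetric")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, substitution = substitution),
            class = "scoring_scheme")
}

#' BLOSUM62 scheme with affine gap penalties
#'
#' Convenience constructor wrapping the BLOSUM62 substitution table shipped
#' with Biostrings, with gap open -10 and gap extension -0.5.
#'
#' @param gap_open,gap_extend Affine gap penalties (<= 0).
#' @return A `scoring_scheme`.
#' @export
scoring_scheme_blosum62 <- function(gap_open = -10, gap_extend = -0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  scoring_scheme(gap_open = gap_open, gap_extend = gap_extend,
                 substitution = e$BLOSUM62)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s; gap_open=%g gap_extend=%g\n",
              if (is.null(x$substitution))
                sprintf("match=%g mismatch=%g", x$match, x$mismatch)
              else "substitution table",
              x$gap_open, x$gap_extend))
  invisible(x)
}

## 26x26 A..Z lookup for the C++ core.  X scores as a mismatch against
## everything (itself included) unless a substitution table says otherwise.
scheme_matrix <- function(s) {
  m <- matrix(s$mismatch, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- s$match
  m["X", ] <- s$mismatch
  m[, "X"] <- s$mismatch
  if (!is.null(s$substitution)) {
    sub <- s$substitution
    res <- intersect(intersect(rownames(sub), colnames(sub)), LETTERS)
    m[res, res] <- sub[res, res]
  }
  m
}

denom_mode <- function(denominator) {
  match(match.arg(denominator, c("alignment", "shorter", "aligned_columns")),
        c("alignment", "shorter", "aligned_columns")) - 1L
}

check_alignable <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), x)
  if (any(bad))
    s1_validation_error(sprintf(
      "%s contains characters outside the amino-acid alphabet", what))
  x
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Aligns two residue strings end-to-end by dynamic programming, maximizing
#' the total score under `scheme`.  Traceback is deterministic: ties prefer
#' the diagonal move, then a gap in the second row, then a gap in the
#' first.  The pair is aligned in a canonical orientation (lexicographically
#' smaller sequence first, rows swapped back afterwards) so that the
#' resulting column counts — and hence percent identity — are invariant
#' under exchanging `a` and `b`.  Either input may be empty.
#'
#' @param a,b Amino-acid strings (X allowed; lowercase accepted).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity_pct` (percent of
#'   alignment columns that are identical non-gap, non-X residue pairs),
#'   and the column counts `matches`, `aln_len`, `aligned_cols`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  a <- check_alignable(a, "first sequence")
  b <- check_alignable(b, "second sequence")
  r <- nw_align_cpp(a, b, scheme_matrix(scheme), scheme$gap_open,
                    scheme$gap_extend)
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score, matches = r$matches, aln_len = r$aln_len,
                 aligned_cols = r$aligned_cols,
                 identity_pct = if (r$aln_len > 0)
                   100 * r$matches / r$aln_len else 0,
                 scheme = scheme),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score: %g  identity: %.1f%% (%d/%d columns)\n",
              x$score, x$identity_pct, x$matches, x$aln_len))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Counts columns where both rows carry the same non-gap, non-X residue.
#' The default denominator is the full alignment length (gap columns
#' included); alternatives are the shorter input sequence or only the
#' residue-residue columns.  A zero-length alignment has identity 0.
#'
#' @param r An `alignment_result`.
#' @param denominator One of `"alignment"`, `"shorter"`,
#'   `"aligned_columns"`.
#' @return Identity percentage in \[0, 100\].
#' @export
percent_identity <- function(r, denominator = "alignment") {
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-" & ca != "X")
  denom <- switch(match.arg(denominator,
                            c("alignment", "shorter", "aligned_columns")),
    alignment = length(ca),
    shorter = min(sum(ca != "-"), sum(cb != "-")),
    aligned_columns = sum(ca != "-" & cb != "-"))
  if (denom <= 0) return(0)
  100 * matches / denom
}

#' Percent identity between two sequences
#'
#' Convenience composition of [global_align()] and [percent_identity()],
#' computed without materializing the aligned strings.
#'
#' @inheritParams global_align
#' @param denominator See [percent_identity()].
#' @return Identity percentage in \[0, 100\].
#' @export
identity_between <- function(a, b, scheme = scoring_scheme(),
                             denominator = "alignment") {
  a <- check_alignable(a, "first sequence")
  b <- check_alignable(b, "second sequence")
  nw_identity_pairs_cpp(c(a, b), 1L, 2L, scheme_matrix(scheme),
                        scheme$gap_open, scheme$gap_extend,
                        denom_mode(denominator))[1]
}

#' Batched percent identities over pairs of a sequence pool
#'
#' Workhorse behind the identity matrices: aligns `seqs[ia[k]]` against
#' `seqs[ib[k]]` for every k and returns the identities.
#'
#' @param seqs Character vector of sequences.
#' @param ia,ib Integer index vectors (1-based) of equal length.
#' @param scheme A [scoring_scheme()].
#' @param denominator See [percent_identity()].
#' @return Numeric vector of identity percentages, one per pair.
#' @export
identity_pairs <- function(seqs, ia, ib, scheme = scoring_scheme(),
                           denominator = "alignment") {
  seqs <- check_alignable(seqs)
  nw_identity_pairs_cpp(seqs, as.integer(ia), as.integer(ib),
                        scheme_matrix(scheme), scheme$gap_open,
                        scheme$gap_extend, denom_mode(denominator))
}

## score-only batch; used by tests cross-checking the DP against oracles
score_pairs <- function(seqs, ia, ib, scheme = scoring_scheme()) {
  seqs <- check_alignable(seqs)
  nw_score_pairs_cpp(seqs, as.integer(ia), as.integer(ib),
                     scheme_matrix(scheme), scheme$gap_open, scheme$gap_extend)
}
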