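## Conservation statistics: inter-domain identity matrices per domain-count
## group, within-position identities, and reference scans against a
## one-domain S1 sequence (e.g. the RNA-binding S1 domain of PNPase).

#' Slice the annotated S1 domains out of each record
#'
#' @param ds An `s1_dataset`.
#' @return A data.frame with columns `accession`, `domain_index` (1-based
#'   position along the chain) and `subsequence`, in chain order.
#' @export
extract_domains <- function(ds) {
  r <- ds$records
  out <- lapply(seq_len(nrow(r)), function(i) {
    b <- r$boundaries[[i]]
    if (nrow(b) == 0) return(NULL)
    data.frame(accession = r$accession[i],
               domain_index = seq_len(nrow(b)),
               subsequence = substring(r$sequence[i], b[, "start"], b[, "end"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(accession = character(0), domain_index = integer(0),
                      subsequence = character(0))
  rownames(out) <- NULL
  out
}

group_records <- function(ds, k) {
  counts <- vapply(ds$records$boundaries, nrow, integer(1))
  ds[counts == k]
}

#' Inter-domain identity matrix for one domain-count group
#'
#' For the group of records with exactly `k` annotated S1 domains, computes
#' the k-by-k matrix of mean percent identities between domain positions.
#' Off-diagonal cell (i, j) averages the identity of domain i of one record
#' against domain j of another over all ordered record pairs, plus (by
#' default) each record's own internal domain i versus domain j pair.
#' Diagonal cell (i, i) is the mean pairwise identity among the domain-i
#' instances of distinct records.
#'
#' Groups larger than `max_records` are reduced to a seeded random
#' subsample of records before the quadratic pair sweep; the subsample seed
#' is recorded in the result.
#'
#' @param ds An `s1_dataset`.
#' @param k Domain count selecting the group (>= 2 records required).
#' @param scheme A [scoring_scheme()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @param include_within_record Include each record's internal cross-domain
#'   pairs in off-diagonal cells (default TRUE); set FALSE for
#'   cross-record-only averages.
#' @param max_records Subsample cap on the group size.
#' @param subsample_seed Seed used when subsampling.
#' @return An `identity_matrix`: list with `group`, `mat` (k x k, percent),
#'   `n_pairs` (k x k pair counts), `n_records`, `denominator`, and
#'   `subsampled`/`subsample_seed`.
#' @export
interdomain_identity_matrix <- function(ds, k, scheme = scoring_scheme(),
                                        denominator = "alignment",
                                        include_within_record = TRUE,
                                        max_records = 500,
                                        subsample_seed = 1L) {
  grp <- group_records(ds, k)
  n <- n_records(grp)
  if (n < 2)
    s1_validation_error(sprintf(
      "insufficient data: %d record(s) with domain count %d (need >= 2)", n, k))
  subsampled <- n > max_records
  if (subsampled) {
    idx <- with_seed(subsample_seed, sample.int(n, max_records))
    grp <- grp[sort(idx)]
    n <- max_records
  }
  dom <- extract_domains(grp)
  ## pool index of domain i of record r: (r-1)*k + i
  pool <- dom$subsequence[order(match(dom$accession, grp$records$accession),
                                dom$domain_index)]
  pidx <- function(r, i) (r - 1L) * k + i

  pr <- utils::combn(n, 2)  # unordered record pairs
  a <- pr[1, ]; b <- pr[2, ]
  ia <- integer(0); ib <- integer(0); cell <- integer(0)
  cid <- function(i, j) (i - 1L) * k + j
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        ia <- c(ia, pidx(a, i)); ib <- c(ib, pidx(b, i))
        cell <- c(cell, rep(cid(i, i), length(a)))
      } else {
        # both orientations across records
        ia <- c(ia, pidx(a, i), pidx(b, i)); ib <- c(ib, pidx(b, j), pidx(a, j))
        cell <- c(cell, rep(cid(i, j), 2 * length(a)))
        if (include_within_record) {
          ia <- c(ia, pidx(seq_len(n), i)); ib <- c(ib, pidx(seq_len(n), j))
          cell <- c(cell, rep(cid(i, j), n))
        }
      }
    }
  }
  ident <- identity_pairs(pool, ia, ib, scheme, denominator)
  mat <- matrix(NA_real_, k, k)
  npair <- matrix(0L, k, k)
  means <- tapply(ident, cell, mean)
  counts <- tapply(ident, cell, length)
  for (nm in names(means)) {
    id <- as.integer(nm)
    i <- (id - 1L) %/% k + 1L
    j <- (id - 1L) %% k + 1L
    mat[i, j] <- mat[j, i] <- means[[nm]]
    npair[i, j] <- npair[j, i] <- counts[[nm]]
  }
  structure(list(group = k, mat = mat, n_pairs = npair, n_records = n,
                 denominator = denominator,
                 include_within_record = include_within_record,
                 subsampled = subsampled,
                 subsample_seed = if (subsampled) subsample_seed else NA_integer_),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> group k=%d, %d records%s\n", x$group,
              x$n_records,
              if (x$subsampled) sprintf(" (subsampled, seed %d)",
                                        x$subsample_seed) else ""))
  print(round(x$mat, 1))
  invisible(x)
}

#' Mean identity among instances of one domain position
#'
#' Mean pairwise identity over all unordered pairs of domain-`i` instances
#' taken from distinct records of the domain-count-`k` group (the diagonal
#' of [interdomain_identity_matrix()]).
#'
#' @inheritParams interdomain_identity_matrix
#' @param i Domain position, 1-based.
#' @return Identity percentage in \[0, 100\].
#' @export
within_position_identity <- function(ds, k, i, scheme = scoring_scheme(),
                                     denominator = "alignment") {
  grp <- group_records(ds, k)
  n <- n_records(grp)
  if (n < 2)
    s1_validation_error(sprintf(
      "insufficient data: %d record(s) with domain count %d (need >= 2)", n, k))
  if (i < 1 || i > k)
    s1_validation_error(sprintf("domain index %d outside 1..%d", i, k))
  dom <- extract_domains(grp)
  inst <- dom$subsequence[dom$domain_index == i]
  pr <- utils::combn(n, 2)
  mean(identity_pairs(inst, pr[1, ], pr[2, ], scheme, denominator))
}

#' Scan records against a one-domain reference sequence
#'
#' For every record, aligns each S1 domain against `ref` and takes the
#' best-identity domain position (ties break to the lowest index).  Per
#' domain-count group, reports the modal best position, the number of
#' records at the mode, and their mean identity.
#'
#' @param ds An `s1_dataset`.
#' @param ref Reference one-domain amino-acid sequence.
#' @param reference_id Label for the reference in outputs.
#' @param scheme A [scoring_scheme()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @return A `ref_scan` data.frame, one row per domain-count group:
#'   `reference_id`, `group`, `n_records`, `modal_index`,
#'   `n_representatives`, `mean_identity`.  The per-record table
#'   (`accession`, `group`, `best_index`, `best_identity`) is attached as
#'   attribute `per_record`.
#' @export
reference_scan <- function(ds, ref, reference_id = "reference",
                           scheme = scoring_scheme(),
                           denominator = "alignment") {
  if (!nzchar(ref)) s1_validation_error("reference sequence is empty")
  dom <- extract_domains(ds)
  if (nrow(dom) == 0)
    s1_validation_error("dataset has no annotated domains to scan")
  pool <- c(ref, dom$subsequence)
  ident <- identity_pairs(pool, rep(1L, nrow(dom)), seq_len(nrow(dom)) + 1L,
                          scheme, denominator)
  counts <- vapply(ds$records$boundaries, nrow, integer(1))
  k_of <- setNames(counts, ds$records$accession)
  per <- do.call(rbind, lapply(split(seq_len(nrow(dom)), dom$accession),
    function(ii) {
      best <- which.max(ident[ii])  # lowest index on ties
      data.frame(accession = dom$accession[ii[1]],
                 group = unname(k_of[dom$accession[ii[1]]]),
                 best_index = dom$domain_index[ii][best],
                 best_identity = ident[ii][best], stringsAsFactors = FALSE)
    }))
  rownames(per) <- NULL
  groups <- sort(unique(per$group))
  res <- do.call(rbind, lapply(groups, function(k) {
    sub <- per[per$group == k, , drop = FALSE]
    tab <- table(factor(sub$best_index, levels = seq_len(k)))
    modal <- as.integer(names(tab)[which.max(tab)])  # lowest index on ties
    at_mode <- sub$best_identity[sub$best_index == modal]
    data.frame(reference_id = reference_id, group = k,
               n_records = nrow(sub), modal_index = modal,
               n_representatives = length(at_mode),
               mean_identity = mean(at_mode), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "per_record") <- per
  class(res) <- c("ref_scan", "data.frame")
  res
}

#' @export
print.ref_scan <- function(x, ...) {
  cat("<ref_scan>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Locate the most conserved domain by three independent statistics
#'
#' Combines an inter-domain identity matrix with one or more reference
#' scans of the same group and reports, with ties broken to the lowest
#' index: the position with maximal within-position (diagonal) identity,
#' the off-diagonal cell with maximal between-position identity, and the
#' modal reference-scan position(s).  Flags whether the locators agree and
#' whether the matrix is degenerate (all cells equal, e.g. cloned records).
#'
#' @param mat An `identity_matrix`.
#' @param scans A `ref_scan`, or a list of them, computed on the same
#'   dataset (rows for other groups are ignored).
#' @return A `conservation_summary` list: `group`, `diag_argmax`,
#'   `offdiag_argmax` (c(i, j)), `refscan_modes` (named integer vector),
#'   `agreement`, `degenerate`.
#' @export
conserved_domain_summary <- function(mat, scans = NULL) {
  k <- mat$group
  m <- mat$mat
  diag_argmax <- which.max(diag(m))
  off <- m
  diag(off) <- -Inf
  flat <- which.max(t(off))  # row-major: earliest (i, j) wins ties
  oi <- (flat - 1L) %/% k + 1L
  oj <- (flat - 1L) %% k + 1L
  pair <- sort(c(oi, oj))
  degenerate <- k > 1 && diff(range(m)) < 1e-9
  modes <- integer(0)
  if (!is.null(scans)) {
    if (inherits(scans, "ref_scan")) scans <- list(scans)
    modes <- vapply(scans, function(s) {
      row <- s[s$group == k, , drop = FALSE]
      if (nrow(row) == 0) NA_integer_ else row$modal_index[1]
    }, integer(1))
    names(modes) <- vapply(scans, function(s) s$reference_id[1], character(1))
    modes <- modes[!is.na(modes)]
  }
  agreement <- length(unique(c(diag_argmax, modes))) <= 1 &&
    diag_argmax %in% pair
  structure(list(group = k, diag_argmax = as.integer(diag_argmax),
                 offdiag_argmax = as.integer(pair), refscan_modes = modes,
                 agreement = agreement, degenerate = degenerate),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> group k=%d\n", x$group))
  cat(sprintf("  within-position (diagonal) max at domain %d\n", x$diag_argmax))
  cat(sprintf("  between-position max at pair {%d, %d}\n",
              x$offdiag_argmax[1], x$offdiag_argmax[2]))
  if (length(x$refscan_modes) > 0)
    cat(sprintf("  reference-scan mode(s): %s\n",
                paste(names(x$refscan_modes), x$refscan_modes,
                      sep = "=", collapse = ", ")))
  if (x$degenerate) cat("  degenerate (uniform identity)\n")
  cat(sprintf("  locators agree: %s\n", x$agreement))
  invisible(x)
}

#' Write an identity matrix as TSV (long format) and JSON
#'
#' @param mat An `identity_matrix`.
#' @param tsv_path Output TSV (columns i, j, mean_identity, n_pairs).
#' @param json_path Optional JSON path.
#' @param header Optional `#`-prefixed comment line(s).
#' @return Invisibly, `mat`.
#' @export
write_identity_matrix <- function(mat, tsv_path, json_path = NULL,
                                  header = NULL) {
  k <- mat$group
  long <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(i = i, j = seq_len(k), mean_identity = mat$mat[i, ],
               n_pairs = mat$n_pairs[i, ])))
  con <- file(tsv_path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(group = k, matrix = mat$mat,
                              n_pairs = mat$n_pairs,
                              n_records = mat$n_records,
                              denominator = mat$denominator),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(mat)
}
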