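#' Construct a dataset of annotated protein records
#'
#' An `s1_dataset` bundles protein sequences with the per-record annotation
#' needed for the S1-domain census: protein and gene names, taxonomic
#' lineage, phylum, the ordered S1-domain boundary list (1-based, inclusive,
#' UniProt convention) and a flag for annotated non-S1 domains.
#'
#' @param records A data.frame with columns `accession`, `protein_name`,
#'   `gene_name`, `phylum`, `sequence`, `has_extra_domains` (logical), and
#'   list-columns `lineage` (character vectors, domain to species) and
#'   `boundaries` (integer matrices with columns `start`, `end`).
#' @param provenance Free-text provenance tag (source file, release label).
#' @return An object of class `s1_dataset`.
#' @export
s1_dataset <- function(records, provenance = "") {
  ds <- structure(list(records = records, provenance = provenance),
                  class = "s1_dataset")
  validate_dataset(ds)
  ds
}

empty_records <- function(n = 0) {
  data.frame(
    accession = character(n), protein_name = character(n),
    gene_name = character(n), phylum = character(n),
    sequence = character(n), has_extra_domains = logical(n),
    lineage = I(rep(list(character(0)), n)),
    boundaries = I(rep(list(empty_boundaries()), n)),
    stringsAsFactors = FALSE
  )
}

empty_boundaries <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

#' @export
print.s1_dataset <- function(x, ...) {
  cat(sprintf("<s1_dataset> %d record(s)", nrow(x$records)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  if (nrow(x$records) > 0) {
    k <- vapply(x$records$boundaries, nrow, integer(1))
    cat("  domain counts: ",
        paste(names(table(k)), table(k), sep = "x", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
`[.s1_dataset` <- function(x, i, ...) {
  structure(list(records = x$records[i, , drop = FALSE],
                 provenance = x$provenance),
            class = "s1_dataset")
}

#' Number of records in a dataset
#' @param ds An `s1_dataset`.
#' @return Integer count.
#' @export
n_records <- function(ds) nrow(ds$records)

#' Validate dataset invariants
#'
#' Checks accession uniqueness, the residue alphabet (20 amino acids plus
#' X), and that every boundary pair satisfies
#' `1 <= start <= end <= nchar(sequence)`, is sorted by start and
#' non-overlapping.
#'
#' @param ds An `s1_dataset`.
#' @return `ds`, invisibly; signals a validation error otherwise.
#' @export
validate_dataset <- function(ds) {
  r <- ds$records
  need <- c("accession", "protein_name", "gene_name", "phylum", "sequence",
            "has_extra_domains", "lineage", "boundaries")
  miss <- setdiff(need, names(r))
  if (length(miss) > 0)
    s1_format_error(paste("dataset records missing column(s):",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(r$accession))
    s1_validation_error(sprintf(
      "duplicated accession: %s", r$accession[duplicated(r$accession)][1]))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), r$sequence)
  if (any(bad))
    s1_validation_error(sprintf(
      "sequence for %s contains characters outside the amino-acid alphabet",
      r$accession[which(bad)[1]]))
  for (i in seq_len(nrow(r))) {
    check_boundaries(r$boundaries[[i]], nchar(r$sequence[i]), r$accession[i])
  }
  invisible(ds)
}

check_boundaries <- function(b, seq_len, accession) {
  if (nrow(b) == 0) return(invisible(b))
  if (any(b[, "start"] < 1) || any(b[, "end"] < b[, "start"]))
    s1_validation_error(sprintf(
      "invalid domain boundary for %s: start must satisfy 1 <= start <= end",
      accession))
  if (!is.na(seq_len) && any(b[, "end"] > seq_len))
    s1_validation_error(sprintf(
      "domain boundary for %s exceeds sequence length (%d)",
      accession, seq_len))
  if (nrow(b) > 1) {
    if (is.unsorted(b[, "start"], strictly = TRUE))
      s1_validation_error(sprintf(
        "domain boundaries for %s are not sorted by start", accession))
    if (any(b[-1, "start"] <= b[-nrow(b), "end"]))
      s1_validation_error(sprintf(
        "domain boundaries for %s overlap", accession))
  }
  invisible(b)
}

#' Read protein sequences from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header.
#' Sequences are uppercased; wrapped lines are joined.  Residues must come
#' from the 20-letter amino-acid alphabet, with X tolerated (and flagged
#' downstream: X never counts as an identity match).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping accession to sequence; empty
#'   files yield an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) s1_io_error(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  empty_hdr <- hdr & !grepl("^>\\s*\\S", lines)
  if (any(empty_hdr))
    s1_format_error(sprintf(
      "malformed FASTA header (no text after '>') at line %d",
      which(empty_hdr)[1]))
  if (!any(hdr)) {
    if (any(nzchar(trimws(lines))))
      s1_format_error("not FASTA-formatted: sequence data before any header")
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
  if (any(bad))
    s1_validation_error(sprintf(
      "sequence for %s contains non-amino-acid characters (other than X)",
      names(seqs)[which(bad)[1]]))
  seqs
}

#' Read per-record annotation from a metadata TSV
#'
#' The table must have a header row with columns `accession`,
#' `protein_name`, `gene_name`, `lineage` (semicolon-separated taxon names),
#' `phylum`, `s1_boundaries` (comma-separated `start-end` tokens, 1-based
#' inclusive; empty string for none) and `has_extra_domains`
#' (`true`/`false`).
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A data.frame of partial records (every field except the
#'   sequence), with list-columns `lineage` and `boundaries`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) s1_io_error(paste("file not found:", path))
  tb <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", colClasses = "character",
                   check.names = FALSE, na.strings = NULL,
                   fileEncoding = "UTF-8")
  need <- c("accession", "protein_name", "gene_name", "lineage", "phylum",
            "s1_boundaries", "has_extra_domains")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0)
    s1_format_error(paste("metadata missing column(s):",
                          paste(miss, collapse = ", ")))
  n <- nrow(tb)
  lineage <- lapply(tb$lineage, function(x) {
    if (!nzchar(x)) character(0) else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  })
  boundaries <- Map(parse_boundaries, tb$s1_boundaries, tb$accession)
  hx <- tolower(trimws(tb$has_extra_domains))
  bad <- !hx %in% c("true", "false")
  if (any(bad))
    s1_format_error(sprintf(
      "has_extra_domains for %s must be 'true' or 'false' (got '%s')",
      tb$accession[which(bad)[1]], tb$has_extra_domains[which(bad)[1]]))
  data.frame(
    accession = tb$accession, protein_name = tb$protein_name,
    gene_name = tb$gene_name, phylum = tb$phylum,
    has_extra_domains = hx == "true",
    lineage = I(unname(lineage)), boundaries = I(unname(boundaries)),
    stringsAsFactors = FALSE
  )
}

parse_boundaries <- function(s, accession) {
  s <- trimws(s)
  if (!nzchar(s)) return(empty_boundaries())
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  ok <- grepl("^[0-9]+-[0-9]+$", toks)
  if (any(!ok))
    s1_validation_error(sprintf(
      "unparsable boundary token '%s' for %s", toks[which(!ok)[1]], accession))
  parts <- do.call(rbind, strsplit(toks, "-", fixed = TRUE))
  b <- matrix(as.integer(parts), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  check_boundaries(b, NA_integer_, accession)
  b
}

#' Merge sequences with metadata into a dataset
#'
#' Keeps only accessions present in both inputs; the number dropped from
#' each side is reported via [message()].  Boundary pairs are validated
#' against the sequence length.
#'
#' @param seqs Named character vector (accession to sequence), as returned
#'   by [read_fasta()].
#' @param meta Partial-record data.frame, as returned by [read_metadata()].
#' @param provenance Provenance tag for the resulting dataset.
#' @return An `s1_dataset` containing the intersection.
#' @export
merge_dataset <- function(seqs, meta, provenance = "merged") {
  common <- intersect(names(seqs), meta$accession)
  d_seq <- length(seqs) - length(common)
  d_meta <- nrow(meta) - length(common)
  if (d_seq > 0 || d_meta > 0)
    message(sprintf(
      "merge: dropped %d sequence-only and %d metadata-only accession(s)",
      d_seq, d_meta))
  meta <- meta[match(common, meta$accession), , drop = FALSE]
  rec <- data.frame(
    accession = common, protein_name = meta$protein_name,
    gene_name = meta$gene_name, phylum = meta$phylum,
    sequence = unname(seqs[common]),
    has_extra_domains = meta$has_extra_domains,
    lineage = I(unname(meta$lineage)), boundaries = I(unname(meta$boundaries)),
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  s1_dataset(rec, provenance)
}

#' Read a dataset from FASTA plus metadata TSV
#'
#' @param fasta_path FASTA file of sequences.
#' @param meta_path Metadata TSV (see [read_metadata()]).
#' @param provenance Provenance tag; defaults to the FASTA file name.
#' @return An `s1_dataset`.
#' @export
read_dataset <- function(fasta_path, meta_path,
                         provenance = basename(fasta_path)) {
  merge_dataset(read_fasta(fasta_path), read_metadata(meta_path), provenance)
}

#' Write a dataset to FASTA plus metadata TSV
#'
#' Round-trips with [read_dataset()]: reading the written pair yields an
#' equal dataset.
#'
#' @param ds An `s1_dataset`.
#' @param fasta_path Output FASTA path.
#' @param meta_path Output TSV path.
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, fasta_path, meta_path) {
  r <- ds$records
  for (p in c(fasta_path, meta_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) s1_io_error(paste("directory does not exist:", dir))
  }
  ss <- Biostrings::BStringSet(setNames(r$sequence, r$accession))
  Biostrings::writeXStringSet(ss, fasta_path)
  tb <- data.frame(
    accession = r$accession, protein_name = r$protein_name,
    gene_name = r$gene_name,
    lineage = vapply(r$lineage, paste, character(1), collapse = ";"),
    phylum = r$phylum,
    s1_boundaries = vapply(r$boundaries, format_boundaries, character(1)),
    has_extra_domains = ifelse(r$has_extra_domains, "true", "false"),
    stringsAsFactors = FALSE
  )
  write.table(tb, meta_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(ds)
}

format_boundaries <- function(b) {
  if (nrow(b) == 0) return("")
  paste(sprintf("%d-%d", b[, "start"], b[, "end"]), collapse = ",")
}
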