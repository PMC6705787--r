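## Record-selection rules for the S1 dataset.  Each rule is a pure subset
## operation on an s1_dataset; build_dataset() chains them in a fixed order
## and reports per-rule attrition.

#' Protein-name keywords selecting ribosomal protein S1 records
#'
#' The eight protein-name keywords used to query candidate S1 records;
#' matching is substring-based on the lowercased protein name.
#'
#' @return Character vector of lowercase keywords.
#' @export
s1_keywords <- function() {
  c("30s ribosomal protein s1",
    "ribosomal protein s1",
    "30s ribosomal protein s1 (ec 1.17.1.2)",
    "30s ribosomal protein s1 (ribosomal protein s1)",
    "ribosomal protein s1 domain protein",
    "rna binding protein s1",
    "rna binding s1 domain protein",
    "s1 rna binding domain protein")
}

#' Keep records whose protein name contains an S1 keyword
#'
#' A record is kept iff its lowercased protein name contains at least one
#' of [s1_keywords()] as a substring.
#'
#' @param ds An `s1_dataset`.
#' @return The filtered `s1_dataset`.
#' @export
keyword_filter <- function(ds) {
  nm <- tolower(ds$records$protein_name)
  keep <- rep(FALSE, length(nm))
  for (kw in s1_keywords()) keep <- keep | grepl(kw, nm, fixed = TRUE)
  ds[keep]
}

#' Keep records encoded by the rpsA gene or a numbered analog
#'
#' A record is kept iff its gene name matches, case-insensitively and as a
#' full token, `rpsA` optionally followed by an underscore and digits
#' (rpsA, rpsA_1, rpsA_2, ...).  Substring hits such as "rpsAB" are
#' excluded.
#'
#' @param ds An `s1_dataset`.
#' @return The filtered `s1_dataset`.
#' @export
gene_filter <- function(ds) {
  keep <- grepl("^rpsa(_[0-9]+)?$", trimws(ds$records$gene_name),
                ignore.case = TRUE)
  ds[keep]
}

#' Drop records from candidate taxa
#'
#' Provisional taxa lack the information required to assign a phylum under
#' bacterial nomenclature.  A record is dropped iff any lineage element or
#' the phylum field contains (case-insensitively) the stem `candidat`,
#' which catches both "candidate division ..." and "Candidatus ..." names;
#' set `stem = FALSE` to match only the literal word "candidate".
#'
#' @param ds An `s1_dataset`.
#' @param stem Use the stem `candidat` (default) rather than `candidate`.
#' @return The filtered `s1_dataset`.
#' @export
candidate_filter <- function(ds, stem = TRUE) {
  pat <- if (stem) "candidat" else "candidate"
  hit <- vapply(seq_len(nrow(ds$records)), function(i) {
    fields <- c(ds$records$lineage[[i]], ds$records$phylum[i])
    any(grepl(pat, tolower(fields), fixed = TRUE))
  }, logical(1))
  ds[!hit]
}

#' Drop records without any annotated S1 domain
#'
#' Records whose domain count is zero carry no boundary information and are
#' removed from the analysis dataset.
#'
#' @param ds An `s1_dataset`.
#' @return The filtered `s1_dataset`.
#' @export
domain_presence_filter <- function(ds) {
  k <- vapply(ds$records$boundaries, nrow, integer(1))
  ds[k >= 1]
}

#' Drop records carrying annotated non-S1 domains
#'
#' @param ds An `s1_dataset`.
#' @return The filtered `s1_dataset`.
#' @export
extra_domain_filter <- function(ds) {
  ds[!ds$records$has_extra_domains]
}

#' Keep records with six-character accessions
#'
#' Optional strictness proxy for fully annotated database records; off by
#' default because it is meaningless for synthetic accessions.
#'
#' @param ds An `s1_dataset`.
#' @return The filtered `s1_dataset`.
#' @export
accession_filter <- function(ds) {
  keep <- grepl("^[A-Za-z0-9]{6}$", ds$records$accession)
  ds[keep]
}

#' Build the analysis dataset by applying all selection rules in order
#'
#' Applies keyword, gene, (optionally accession,) candidate-taxon,
#' domain-presence and extra-domain rules sequentially and records the
#' attrition at each step.
#'
#' @param ds An `s1_dataset`.
#' @param candidate_stem Passed to [candidate_filter()].
#' @param strict_accession Also apply [accession_filter()] (after the gene
#'   rule).
#' @return A list with elements `dataset` (the filtered `s1_dataset`) and
#'   `report` (a `filter_report`).
#' @export
build_dataset <- function(ds, candidate_stem = TRUE,
                          strict_accession = FALSE) {
  rules <- list(
    keyword = keyword_filter,
    gene = gene_filter,
    candidate = function(d) candidate_filter(d, stem = candidate_stem),
    domain_presence = domain_presence_filter,
    extra_domain = extra_domain_filter
  )
  if (strict_accession)
    rules <- append(rules, list(accession = accession_filter), after = 2)
  out <- ds
  rows <- vector("list", length(rules))
  dropped <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    before <- out
    out <- rules[[i]](out)
    drop_acc <- setdiff(before$records$accession, out$records$accession)
    rows[[i]] <- data.frame(
      rule = names(rules)[i],
      n_in = n_records(before), n_out = n_records(out),
      n_dropped = length(drop_acc), stringsAsFactors = FALSE)
    dropped[[i]] <- drop_acc
  }
  report <- do.call(rbind, rows)
  names(dropped) <- names(rules)
  attr(report, "dropped") <- dropped
  class(report) <- c("filter_report", "data.frame")
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Accessions dropped by each rule of a filter report
#' @param report A `filter_report`.
#' @return Named list of character vectors, one per rule.
#' @export
dropped_accessions <- function(report) attr(report, "dropped")

#' Write a filter report as TSV plus a dropped-accessions sidecar
#'
#' @param report A `filter_report`.
#' @param path Output TSV path (columns rule, n_in, n_out, n_dropped).
#' @param sidecar_path Optional text file listing `rule<TAB>accession` for
#'   every dropped record.
#' @return Invisibly, `report`.
#' @export
write_filter_report <- function(report, path, sidecar_path = NULL) {
  write.table(as.data.frame(report)[, c("rule", "n_in", "n_out", "n_dropped")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar_path)) {
    d <- dropped_accessions(report)
    lines <- unlist(lapply(names(d), function(r) {
      if (length(d[[r]]) == 0) character(0) else paste(r, d[[r]], sep = "\t")
    }))
    writeLines(lines, sidecar_path)
  }
  invisible(report)
}
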