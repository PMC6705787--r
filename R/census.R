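#' Number of S1 domains per record
#'
#' The domain count is the number of annotated boundary pairs.  In the
#' family of ribosomal proteins S1 the count ranges from one to six; larger
#' values are legal but flagged with a warning.
#'
#' @param ds An `s1_dataset`.
#' @return Integer vector, one count per record.
#' @export
domain_count <- function(ds) {
  k <- vapply(ds$records$boundaries, nrow, integer(1))
  if (any(k > 6))
    warning(sprintf(
      "%d record(s) have more than six S1 domains (outside the observed 1-6 range)",
      sum(k > 6)))
  k
}

#' Phylum-by-domain-count census of a dataset
#'
#' Groups records by the number of S1 domains and tabulates occupancy per
#' (phylum, domain count) cell together with sequence-length statistics.
#'
#' @param ds A filtered `s1_dataset` (every record with >= 1 domain).
#' @return A `census_table`: list with `cells` (long-format data.frame:
#'   phylum, domain_count, n, pct_of_total, mean_len, min_len, max_len),
#'   `phylum_totals`, `count_totals` (named vectors) and `grand_total`.
#'   Percentages are reported to one decimal place.
#' @export
build_census <- function(ds) {
  r <- ds$records
  k <- domain_count(ds)
  if (any(k < 1))
    s1_validation_error(
      "dataset contains records without S1 domains; apply domain_presence_filter first")
  len <- nchar(r$sequence)
  key <- interaction(r$phylum, k, drop = TRUE, sep = "\r")
  cells <- do.call(rbind, lapply(levels(key), function(lv) {
    i <- key == lv
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    data.frame(phylum = parts[1], domain_count = as.integer(parts[2]),
               n = sum(i), mean_len = mean(len[i]),
               min_len = min(len[i]), max_len = max(len[i]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells))
    cells <- data.frame(phylum = character(0), domain_count = integer(0),
                        n = integer(0), mean_len = numeric(0),
                        min_len = numeric(0), max_len = numeric(0))
  cells <- cells[order(cells$domain_count, cells$phylum), , drop = FALSE]
  rownames(cells) <- NULL
  total <- sum(cells$n)
  cells$pct_of_total <- if (total > 0) round(100 * cells$n / total, 1) else numeric(0)
  cells <- cells[, c("phylum", "domain_count", "n", "pct_of_total",
                     "mean_len", "min_len", "max_len")]
  structure(list(
    cells = cells,
    phylum_totals = c(tapply(cells$n, cells$phylum, sum)),
    count_totals = c(tapply(cells$n, cells$domain_count, sum)),
    grand_total = total
  ), class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("<census_table> %d records, %d phyla, domain counts %s\n",
              x$grand_total, length(x$phylum_totals),
              paste(names(x$count_totals), collapse = ",")))
  print.data.frame(x$cells, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fraction of records per domain count
#'
#' @param ct A `census_table`.
#' @return Named numeric vector: percent of all records falling in each
#'   domain-count group, to one decimal place.
#' @export
count_shares <- function(ct) {
  r <- round(100 * ct$count_totals / ct$grand_total, 1)
  setNames(as.numeric(r), names(r))
}

#' Sequence-length summary for one domain-count group
#'
#' @param ds An `s1_dataset`.
#' @param group Domain count selecting the group.
#' @return Named numeric vector `c(mean, min, max)` of sequence length.
#' @export
length_summary <- function(ds, group) {
  k <- vapply(ds$records$boundaries, nrow, integer(1))
  len <- nchar(ds$records$sequence[k == group])
  if (length(len) == 0)
    s1_validation_error(sprintf("no records with domain count %d", group))
  c(mean = mean(len), min = min(len), max = max(len))
}

#' Write a census table as TSV and JSON
#'
#' @param ct A `census_table`.
#' @param tsv_path Output TSV path (long format).
#' @param json_path Optional JSON path (cells plus marginals).
#' @param header Optional comment line(s) prefixed with `#` at the top of
#'   the TSV.
#' @return Invisibly, `ct`.
#' @export
write_census <- function(ct, tsv_path, json_path = NULL, header = NULL) {
  con <- file(tsv_path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(ct$cells, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      cells = ct$cells,
      phylum_totals = as.list(ct$phylum_totals),
      count_totals = as.list(ct$count_totals),
      grand_total = ct$grand_total
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(ct)
}
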