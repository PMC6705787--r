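#' Fetch a protein sequence from UniProt
#'
#' Downloads the FASTA record for one accession from the UniProt REST
#' service.  Network access is required; on any transport failure an I/O
#' error is signalled.  Intended for pinned-accession checks against
#' canonical references (e.g. the 110-residue one-domain S1 protein of
#' *Mycoplasma auris*, accession N9VCN6).
#'
#' @param accession UniProt accession, e.g. `"N9VCN6"`.
#' @param timeout Transfer timeout in seconds.
#' @return Named character vector mapping the FASTA header token to the
#'   uppercased sequence.
#' @export
fetch_uniprot_sequence <- function(accession, timeout = 30) {
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  ok <- tryCatch(
    utils::download.file(url, tmp, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(tmp) || file.size(tmp) == 0)
    s1_io_error(sprintf("could not retrieve %s from UniProt", accession))
  ss <- Biostrings::readBStringSet(tmp)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}
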