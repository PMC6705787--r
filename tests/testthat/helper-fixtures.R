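# In-code fixtures: tiny hand-built records and datasets.

make_record <- function(accession, sequence = "MKVLQAAA",
                        protein_name = "30S ribosomal protein S1",
                        gene_name = "rpsA",
                        phylum = "Proteobacteria",
                        lineage = c("Bacteria", phylum, "Testus organismus"),
                        boundaries = matrix(c(1L, nchar(sequence)), ncol = 2,
                                            dimnames = list(NULL,
                                                            c("start", "end"))),
                        has_extra_domains = FALSE) {
  data.frame(accession = accession, protein_name = protein_name,
             gene_name = gene_name, phylum = phylum, sequence = sequence,
             has_extra_domains = has_extra_domains,
             lineage = I(list(lineage)), boundaries = I(list(boundaries)),
             stringsAsFactors = FALSE)
}

make_dataset <- function(..., provenance = "fixture") {
  s1_dataset(do.call(rbind, list(...)), provenance)
}

bounds <- function(...) {
  v <- as.integer(c(...))
  matrix(v, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

empty_bounds <- function() bounds()

# A dataset of n identical clones of one multi-domain record.
clone_dataset <- function(n, sequence, boundaries) {
  recs <- do.call(rbind, lapply(seq_len(n), function(i)
    make_record(sprintf("CLN%03d", i), sequence = sequence,
                boundaries = boundaries)))
  s1_dataset(recs, "clones")
}

six_domain_profile <- function() {
  data.frame(phylum = "Proteobacteria", domain_count = 6L, weight = 1,
             stringsAsFactors = FALSE)
}
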