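Package: s1census
Title: Domain Architecture Census and Conservation Analysis of Bacterial
    Ribosomal Protein S1
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles, filters and analyses annotated multi-domain protein
    records for the family of bacterial 30S ribosomal proteins S1, whose
    RNA-binding S1 (OB-fold) domain occurs in tandem one to six times per
    chain.  Provides record selection rules (protein-name keywords, rpsA
    gene, candidate-taxon removal, domain-presence and extra-domain
    checks) with a per-rule attrition report, a global pairwise aligner
    (Needleman-Wunsch, linear or affine gaps) with percent-identity
    computation, a phylum-by-domain-count census with length statistics,
    inter-domain identity matrices and reference scans that locate the
    most conserved repeat, and a seeded simulator of multi-domain
    families with known ground truth so every stage is testable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
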