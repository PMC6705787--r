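test_that("read_fasta parses single, wrapped and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A1", "MKV"), f)
  expect_equal(read_fasta(f), c(A1 = "MKV"))

  writeLines(c(">A1", "mkv", "lq"), f)
  expect_equal(read_fasta(f), c(A1 = "MKVLQ"))

  writeLines(c(">A1 some description here", "MKV"), f)
  expect_equal(read_fasta(f), c(A1 = "MKV"))

  file.create(f)
  expect_length(read_fasta(f), 0)
})

test_that("read_fasta rejects malformed headers and bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A1", "MKV", ">", "ACDE"), f)
  err <- expect_error(read_fasta(f), class = "s1_format_error")
  expect_match(conditionMessage(err), "line 3")

  writeLines(c(">A1", "MKB2"), f)
  err <- expect_error(read_fasta(f), class = "s1_validation_error")
  expect_match(conditionMessage(err), "A1")

  # X is tolerated
  writeLines(c(">A1", "MKXV"), f)
  expect_equal(read_fasta(f), c(A1 = "MKXV"))
})

test_that("read_metadata parses boundaries, lineage and flags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("accession", "protein_name", "gene_name", "lineage", "phylum",
          "s1_boundaries", "has_extra_domains", sep = "\t"),
    paste("P1", "30S ribosomal protein S1", "rpsA",
          "Bacteria;Proteobacteria;Escherichia coli", "Proteobacteria",
          "1-70,80-150", "false", sep = "\t"),
    paste("P2", "ribosomal protein S1", "rpsA_1", "Bacteria;Firmicutes",
          "Firmicutes", "", "true", sep = "\t")), f)
  m <- read_metadata(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$boundaries[[1]],
               bounds(1, 70, 80, 150))
  expect_equal(nrow(m$boundaries[[2]]), 0)
  expect_equal(m$lineage[[1]],
               c("Bacteria", "Proteobacteria", "Escherichia coli"))
  expect_equal(m$has_extra_domains, c(FALSE, TRUE))
})

test_that("read_metadata reports missing columns and bad boundary tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tprotein_name", "P1\tx"), f)
  expect_error(read_metadata(f), class = "s1_format_error")

  hdr <- paste("accession", "protein_name", "gene_name", "lineage", "phylum",
               "s1_boundaries", "has_extra_domains", sep = "\t")
  writeLines(c(hdr, paste("P1", "n", "g", "Bacteria", "X", "70-1", "false",
                          sep = "\t")), f)
  err <- expect_error(read_metadata(f), class = "s1_validation_error")
  expect_match(conditionMessage(err), "P1")

  writeLines(c(hdr, paste("P1", "n", "g", "Bacteria", "X", "1-70,zz", "false",
                          sep = "\t")), f)
  err <- expect_error(read_metadata(f), class = "s1_validation_error")
  expect_match(conditionMessage(err), "zz")
})

test_that("merge keeps the intersection and validates boundary extents", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("accession", "protein_name", "gene_name", "lineage", "phylum",
               "s1_boundaries", "has_extra_domains", sep = "\t")
  writeLines(c(hdr,
    paste("B", "n", "g", "Bacteria", "X", "1-3", "false", sep = "\t"),
    paste("C", "n", "g", "Bacteria", "X", "1-3", "false", sep = "\t")), f)
  meta <- read_metadata(f)
  seqs <- c(A = "MKVL", B = "ACDEF")
  ds <- suppressMessages(merge_dataset(seqs, meta))
  expect_equal(ds$records$accession, "B")
  expect_equal(ds$records$sequence, "ACDEF")

  # disjoint inputs give an empty dataset
  ds0 <- suppressMessages(merge_dataset(c(Z = "MK"), meta))
  expect_equal(n_records(ds0), 0)

  # boundary beyond the sequence end is rejected
  writeLines(c(hdr,
    paste("B", "n", "g", "Bacteria", "X", "1-200", "false", sep = "\t")), f)
  expect_error(suppressMessages(merge_dataset(seqs, read_metadata(f))),
               class = "s1_validation_error")
})

test_that("merge is order-independent", {
  r1 <- make_record("A", sequence = "MKVLQ")
  r2 <- make_record("B", sequence = "ACDEF")
  seqs <- c(A = "MKVLQ", B = "ACDEF")
  ds <- make_dataset(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  m1 <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f1, m1)
  meta <- read_metadata(m1)
  a <- merge_dataset(seqs, meta)
  b <- merge_dataset(rev(seqs), meta[2:1, ])
  expect_setequal(a$records$accession, b$records$accession)
  ord <- match(a$records$accession, b$records$accession)
  expect_equal(a$records$sequence, b$records$sequence[ord])
})

test_that("write/read round trip is the identity on valid datasets", {
  ds <- make_dataset(
    make_record("A", sequence = "MKVLQACDE", boundaries = bounds(1, 4, 6, 9)),
    make_record("B", sequence = "MXKVA", gene_name = "rpsA_2",
                phylum = "Firmicutes"),
    make_record("C", sequence = "AAAA", has_extra_domains = TRUE))
  f <- withr::local_tempfile(fileext = ".fasta")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f, m)
  back <- read_dataset(f, m)
  expect_equal(back$records$accession, ds$records$accession)
  expect_equal(back$records$sequence, ds$records$sequence)  # X preserved
  expect_equal(back$records$boundaries, ds$records$boundaries,
               ignore_attr = TRUE)
  expect_equal(back$records$lineage, ds$records$lineage, ignore_attr = TRUE)
  expect_equal(back$records$has_extra_domains, ds$records$has_extra_domains)

  # empty dataset round-trips to empty files
  e <- make_dataset(make_record("Z"))[0]
  write_dataset(e, f, m)
  expect_equal(n_records(read_dataset(f, m)), 0)
})

test_that("dataset invariants are enforced", {
  expect_error(make_dataset(make_record("A"), make_record("A")),
               class = "s1_validation_error")
  expect_error(make_record("A", sequence = "MKV",
                           boundaries = bounds(1, 5)) |> make_dataset(),
               class = "s1_validation_error")
  expect_error(make_record("A", sequence = "MKVLQW",
                           boundaries = bounds(1, 4, 3, 6)) |> make_dataset(),
               class = "s1_validation_error")
})
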