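test_that("extract_domains slices 1-based inclusive boundaries", {
  ds <- make_dataset(make_record("A", sequence = "AAACCCGGG",
                                 boundaries = bounds(1, 3, 7, 9)))
  d <- extract_domains(ds)
  expect_equal(d$subsequence, c("AAA", "GGG"))
  expect_equal(d$domain_index, c(1L, 2L))

  whole <- make_dataset(make_record("B", sequence = "MKVLQ",
                                    boundaries = bounds(1, 5)))
  expect_equal(extract_domains(whole)$subsequence, "MKVLQ")

  # assembly round trip: extraction returns the generator's domains
  doms <- replicate(6, random_seq(70))
  asm <- assemble_protein(doms, linker_length = 10, seed = 3)
  ds6 <- make_dataset(make_record("C", sequence = asm$sequence,
                                  boundaries = asm$boundaries))
  expect_equal(extract_domains(ds6)$subsequence, doms)
  expect_equal(extract_domains(ds6)$domain_index, 1:6)
})

test_that("clone dataset gives a degenerate all-100 diagonal matrix", {
  doms <- replicate(3, random_seq(40))
  asm <- assemble_protein(doms, linker_length = 5, seed = 4)
  ds <- clone_dataset(4, asm$sequence, asm$boundaries)
  mat <- interdomain_identity_matrix(ds, 3)
  expect_equal(diag(mat$mat), rep(100, 3))
  expect_equal(mat$mat, t(mat$mat))
  expect_true(all(mat$mat >= 0 & mat$mat <= 100))

  # identical strings in every domain slot: every cell exactly 100
  same <- assemble_protein(rep(random_seq(40), 3), linker_length = 5,
                           seed = 6)
  ds_same <- clone_dataset(3, same$sequence, same$boundaries)
  mat_same <- interdomain_identity_matrix(ds_same, 3)
  expect_equal(mat_same$mat, matrix(100, 3, 3))
  sm <- conserved_domain_summary(mat_same)
  expect_true(sm$degenerate)
})

test_that("identity matrix is symmetric and permutation-invariant", {
  fam <- simulate_dataset(simulation_config(
    n_records = 8, seed = 21, phylum_profile = six_domain_profile()))
  ds <- fam$dataset
  mat <- interdomain_identity_matrix(ds, 6)
  expect_equal(mat$mat, t(mat$mat))
  perm <- ds[sample(n_records(ds))]
  mat_p <- interdomain_identity_matrix(perm, 6)
  expect_equal(mat_p$mat, mat$mat)
  # pair counts: off-diagonal n^2, diagonal choose(n, 2)
  n <- n_records(ds)
  expect_equal(mat$n_pairs[1, 2], n * n)
  expect_equal(mat$n_pairs[1, 1], choose(n, 2))
})

test_that("insufficient groups raise an explicit error", {
  ds <- make_dataset(make_record("A"))
  expect_error(interdomain_identity_matrix(ds, 1),
               class = "s1_validation_error")
  expect_error(within_position_identity(ds, 1, 1),
               class = "s1_validation_error")
})

test_that("within-position identity matches hand-computed pairs", {
  ds <- make_dataset(
    make_record("A", sequence = "ACDE", boundaries = bounds(1, 4)),
    make_record("B", sequence = "ACDF", boundaries = bounds(1, 4)))
  expect_equal(within_position_identity(ds, 1, 1), 75)
  expect_equal(
    within_position_identity(clone_dataset(3, "ACDE", bounds(1, 4)), 1, 1),
    100)
})

test_that("reference scan finds the planted position and breaks ties low", {
  # one-domain group: best index is always 1
  ds1 <- clone_dataset(3, "MKVLQACDE", bounds(1, 9))
  scan <- reference_scan(ds1, "MKVLQACDE", "self")
  expect_equal(scan$modal_index, 1L)
  expect_equal(scan$mean_identity, 100)

  # all domains equal the reference: tie resolves to index 1
  same <- assemble_protein(rep("MKVLQACDE", 3), linker_length = 4, seed = 2)
  ds_tie <- clone_dataset(2, same$sequence, same$boundaries)
  scan_tie <- reference_scan(ds_tie, "MKVLQACDE", "self")
  per <- attr(scan_tie, "per_record")
  expect_true(all(per$best_index == 1L))
  expect_equal(per$best_identity, rep(100, 2))

  expect_error(reference_scan(ds1, ""), class = "s1_validation_error")
})

test_that("scan against the ancestor ranks the planted index highest", {
  fam <- simulate_dataset(simulation_config(
    n_records = 200, seed = 31, phylum_profile = six_domain_profile()))
  dom <- extract_domains(fam$dataset)
  by_index <- vapply(1:6, function(i) {
    inst <- dom$subsequence[dom$domain_index == i]
    mean(identity_pairs(c(fam$truth$ancestor, inst),
                        rep(1L, length(inst)), seq_along(inst) + 1L))
  }, numeric(1))
  expect_equal(which.max(by_index), fam$truth$planted_index)
  expect_true(all(by_index[fam$truth$planted_index] >
                    by_index[-fam$truth$planted_index]))
})

test_that("locators recover the planted conserved index on small runs", {
  hits <- vapply(1:5, function(seed) {
    fam <- simulate_dataset(simulation_config(
      n_records = 30, seed = 500 + seed,
      phylum_profile = six_domain_profile()))
    mat <- interdomain_identity_matrix(fam$dataset, 6)
    scan <- reference_scan(fam$dataset, fam$truth$ancestor, "ancestor")
    sm <- conserved_domain_summary(mat, scan)
    sm$diag_argmax == 3 && all(sm$offdiag_argmax == c(3, 4)) &&
      sm$refscan_modes[["ancestor"]] == 3
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("summary reports group-restricted locators for k = 2", {
  doms <- replicate(2, random_seq(30))
  asm <- assemble_protein(doms, linker_length = 5, seed = 8)
  ds <- clone_dataset(3, asm$sequence, asm$boundaries)
  sm <- conserved_domain_summary(interdomain_identity_matrix(ds, 2))
  expect_true(all(sm$offdiag_argmax %in% 1:2))
  expect_true(sm$diag_argmax %in% 1:2)
})

test_that("oversized groups are subsampled reproducibly", {
  fam <- simulate_dataset(simulation_config(
    n_records = 12, seed = 41, phylum_profile = six_domain_profile()))
  m1 <- interdomain_identity_matrix(fam$dataset, 6, max_records = 8,
                                    subsample_seed = 9)
  m2 <- interdomain_identity_matrix(fam$dataset, 6, max_records = 8,
                                    subsample_seed = 9)
  expect_true(m1$subsampled)
  expect_equal(m1$n_records, 8)
  expect_equal(m1$mat, m2$mat)
})

test_that("identity matrix serializes to TSV and JSON", {
  fam <- simulate_dataset(simulation_config(
    n_records = 4, seed = 51, phylum_profile = six_domain_profile()))
  mat <- interdomain_identity_matrix(fam$dataset, 6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_identity_matrix(mat, tsv, js, header = "test")
  long <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(long), 36)
  expect_equal(long$mean_identity[long$i == 2 & long$j == 5],
               mat$mat[2, 5])
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$matrix, mat$mat)
})
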