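test_that("feature_table enforces its invariants", {
  tab <- make_table(matrix(1:12, 2, 6))
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab$features), 2)
  expect_equal(length(table_samples(tab)), 2)
  # sample with 2 replicates
  inj <- tab$injections[-1, ]
  expect_error(feature_table(tab$features, inj,
                             tab$intensities[, -1, drop = FALSE]),
               "exactly 3 replicate")
  # m/z outside scan range
  f <- tab$features; f$mz[1] <- 50
  expect_error(feature_table(f, tab$injections, tab$intensities),
               "instrument range")
  # duplicated ids
  f <- tab$features; f$feature_id <- rep("X", 2)
  expect_error(feature_table(f, tab$injections, tab$intensities),
               "duplicate feature_id")
})

test_that("feature table TSV round-trip is the identity, missing included", {
  set.seed(7)
  vals <- matrix(round(runif(60, 10, 1e6), 3), 5, 12)
  vals[sample(60, 9)] <- NA
  tab <- make_table(vals, batch = c("b1", "b1", "b2", "b2"))
  d <- withr::local_tempdir()
  write_feature_table(tab, file.path(d, "ft.tsv"),
                      file.path(d, "bm.tsv"))
  back <- read_feature_table(file.path(d, "ft.tsv"), "HILIC_pos",
                             file.path(d, "bm.tsv"))
  expect_equal(back$intensities, tab$intensities,
               ignore_attr = TRUE)
  expect_equal(back$features$mz, tab$features$mz)
  expect_equal(back$features$rt, tab$features$rt)
  expect_identical(back$injections, tab$injections)
})

test_that("malformed feature tables are rejected with named locations", {
  d <- withr::local_tempdir()
  writeLines(c("mz\ttime\tS1.1\tS1.2\tS1.3",
               "100\t30\t1\toops\t3"), file.path(d, "bad.tsv"))
  expect_error(read_feature_table(file.path(d, "bad.tsv")),
               "non-numeric intensity.*S1.2")
  writeLines(c("mass\ttime\tS1.1", "100\t30\t1"), file.path(d, "hdr.tsv"))
  expect_error(read_feature_table(file.path(d, "hdr.tsv")),
               "malformed header")
  writeLines(c("mz\ttime\tS1.1\tS1.2", "100\t30\t1\t2"),
             file.path(d, "reps.tsv"))
  expect_error(read_feature_table(file.path(d, "reps.tsv")), "S1")
})

test_that("sample table validation and round-trip", {
  s <- make_samples(3)
  d <- withr::local_tempdir()
  write_samples(s, file.path(d, "s.tsv"))
  expect_identical(read_samples(file.path(d, "s.tsv")), s)
  bad <- s; bad$maternal_age[2] <- "40-44"
  write_samples(bad, file.path(d, "bad.tsv"))
  expect_error(read_samples(file.path(d, "bad.tsv")), "40-44")
  dup <- s; dup$sample_id[2] <- dup$sample_id[1]
  write_samples(dup, file.path(d, "dup.tsv"))
  expect_error(read_samples(file.path(d, "dup.tsv")), "duplicate")
})

test_that("packaged reference library loads with positive recomputed masses", {
  lib <- read_reference_library(default_reference_library_path())
  expect_gte(nrow(lib), 19)
  expect_true(all(lib$neutral_mass > 0))
  expect_true(all(lib$mode %in% c("HILIC_pos", "C18_neg")))
})

test_that("pathway DB validation catches structural defects", {
  pdb <- read_pathway_db(default_pathway_db_path())
  expect_length(pdb$pathways, 6)
  expect_true(all(lengths(pdb$pathways) >= 20))
  broken <- pdb
  broken$metabolite_masses <-
    broken$metabolite_masses[-1]
  expect_error(validate_pathway_db(broken), "without mass")
  d <- withr::local_tempdir()
  write_pathway_db(pdb, file.path(d, "pdb.json"))
  back <- read_pathway_db(file.path(d, "pdb.json"))
  expect_equal(back$pathways, pdb$pathways)
  expect_equal(back$metabolite_masses, pdb$metabolite_masses)
})
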