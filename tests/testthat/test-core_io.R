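# Domain types, validation, and TSV/bundle round-trips.

test_that("omic_matrix validates modality ranges and identifiers", {
  v <- matrix(runif(6), 3, 2)
  m <- omic_matrix(v, "meth_beta", paste0("f", 1:3), c("a", "b"))
  expect_s3_class(m, "omic_matrix")
  expect_error(omic_matrix(v * 2, "meth_beta", paste0("f", 1:3), c("a", "b")),
               "\\[0, 1\\]")
  expect_error(omic_matrix(v - 1, "rna_log2", paste0("f", 1:3), c("a", "b")),
               "non-negative")
  v[1, 1] <- NA
  expect_error(omic_matrix(v, "meth_beta", paste0("f", 1:3), c("a", "b")),
               "finite")
  expect_error(omic_matrix(matrix(runif(6), 3, 2), "meth_beta",
                           c("f1", "f1", "f2"), c("a", "b")),
               "unique")
  expect_silent(omic_matrix(matrix(runif(6), 3, 2), "meth_beta",
                            c("f1", "f1", "f2"), c("a", "b"),
                            allow_duplicate_features = TRUE))
})

test_that("proportion_matrix enforces the column-sum policy", {
  a <- random_proportions(3, 4)
  expect_true(all(abs(colSums(a$values) - 1) < 1e-8))
  # sum 0.99 deviates by more than the renormalization band: rejected
  bad <- a$values
  bad[, 2] <- bad[, 2] * 0.99
  expect_error(proportion_matrix(bad, a$row_labels, a$sample_ids),
               "deviation")
  # small deviation renormalized with a warning
  mild <- a$values
  mild[, 1] <- mild[, 1] * (1 + 5e-4)
  expect_warning(fixed <- proportion_matrix(mild, a$row_labels, a$sample_ids),
                 "renormalizing")
  expect_true(all(abs(colSums(fixed$values) - 1) < 1e-12))
  expect_error(proportion_matrix(a$values - 0.5, a$row_labels, a$sample_ids),
               "\\[0, 1\\]")
})

test_that("feature-matrix TSV round-trip is the identity to 1e-9 relative", {
  for (modality in c("meth_beta", "rna_log2")) {
    m <- random_omic(100, 10, modality, seed = 42)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_feature_matrix(m, path)
    back <- read_feature_matrix(path, modality)
    expect_identical(back$feature_ids, m$feature_ids)
    expect_identical(back$sample_ids, m$sample_ids)
    expect_lt(max(abs(back$values - m$values) /
                    pmax(abs(m$values), 1e-12)), 1e-9)
  }
})

test_that("TSV parser names the offending cell and rejects ragged tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "f1\t0.1\t0.2", "f2\tNA\t0.4",
               "f3\t0.5\t0.6"), path)
  expect_error(read_feature_matrix(path, "meth_beta"),
               "'NA' at data row 2, column 's1'")
  writeLines(c("feature_id\ts1\ts2", "f1\t0.1\t0.2", "f2\t0.3"), path)
  expect_error(read_feature_matrix(path, "meth_beta"), "ragged")
  writeLines(c("feature_id\ts1\ts2", "f1\t0.1\t1.7"), path)
  expect_error(read_feature_matrix(path, "meth_beta"), "\\[0, 1\\]")
})

test_that("proportion TSV round-trips and header uses cell_type", {
  a <- random_proportions(4, 6, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proportion_matrix(a, path)
  expect_identical(strsplit(readLines(path, n = 1), "\t")[[1]][1],
                   "cell_type")
  back <- read_proportion_matrix(path)
  expect_equal(back$values, a$values, tolerance = 1e-10)
  expect_identical(back$row_labels, a$row_labels)
})

test_that("dataset bundles round-trip, honor hide_truth, and validate", {
  ds <- small_benchmark(seed = 11, n_datasets = 1)[[1]]
  dir_full <- withr::local_tempdir()
  save_dataset_bundle(ds, dir_full, overwrite = TRUE)
  expect_true(file.exists(file.path(dir_full, "a_true.tsv")))
  meta <- jsonlite::read_json(file.path(dir_full, "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$noise_sd, 0.05)
  expect_equal(meta$seed, 11)

  back <- load_dataset_bundle(dir_full)
  expect_true(has_truth(back))
  expect_equal(back$d_rna$values, ds$d_rna$values, tolerance = 1e-9)
  expect_equal(back$a_true$values, ds$a_true$values, tolerance = 1e-9)
  expect_identical(back$t_met$cell_type_labels, ds$t_met$cell_type_labels)

  # refuse to clobber a non-empty directory without the flag
  expect_error(save_dataset_bundle(ds, dir_full), "non-empty")

  dir_hidden <- withr::local_tempdir()
  save_dataset_bundle(ds, dir_hidden, hide_truth = TRUE, overwrite = TRUE)
  expect_false(file.exists(file.path(dir_hidden, "a_true.tsv")))
  hidden <- load_dataset_bundle(dir_hidden)
  expect_false(has_truth(hidden))
  expect_error(matched_mae(random_proportions(5, 3), hidden$a_true))

  # corrupted truth (column sums 0.9) must fail validation on load
  a_path <- file.path(dir_full, "a_true.tsv")
  lines <- readLines(a_path)
  corrupt <- vapply(lines[-1], function(l) {
    f <- strsplit(l, "\t")[[1]]
    paste(c(f[1], as.numeric(f[-1]) * 0.9), collapse = "\t")
  }, character(1))
  writeLines(c(lines[1], corrupt), a_path)
  expect_error(load_dataset_bundle(dir_full), "deviation")
})

test_that("bundle loading flags sample-id mismatches between omics", {
  ds <- small_benchmark(seed = 12, n_datasets = 1)[[1]]
  dir <- withr::local_tempdir()
  save_dataset_bundle(ds, dir, overwrite = TRUE)
  lines <- readLines(file.path(dir, "d_met.tsv"))
  lines[1] <- sub("S01", "SXX", lines[1])
  writeLines(lines, file.path(dir, "d_met.tsv"))
  expect_error(load_dataset_bundle(dir), "mismatch")
})

test_that("derived seeds separate datasets, stages and runs", {
  expect_false(derive_seed(7, "dataset", 1, "a") ==
                 derive_seed(7, "dataset", 2, "a"))
  expect_identical(derive_seed(7, "x", 3), derive_seed(7, "x", 3))
  s <- vapply(1:200, function(i) derive_seed(1, "ds", i), integer(1))
  expect_false(any(duplicated(s)))
})
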