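# Component matching, proportion averaging, the composed baseline
# pipelines, and the external-program adapter.

test_that("match_components inverts row shuffles and equals brute force", {
  a <- random_proportions(4, 12, seed = 5, labeled = FALSE)
  shift <- c(2, 3, 4, 1)
  b <- permute_rows(a, shift)
  p <- match_components(a, b)
  expect_equal(b$values[p, ], a$values)
  expect_identical(match_components(a, a), 1:4)

  set.seed(6)
  for (i in 1:5) {
    x <- random_proportions(4, 8, seed = 100 + i, labeled = FALSE)
    y <- random_proportions(4, 8, seed = 200 + i, labeled = FALSE)
    got <- match_components(x, y)
    best <- NULL; best_cor <- -Inf
    for (p in enum_perms(4)) {
      v <- cor(as.numeric(x$values), as.numeric(y$values[p, ]))
      if (v > best_cor) { best_cor <- v; best <- p }
    }
    expect_identical(as.integer(got), as.integer(best))
  }
})

test_that("sampled and exhaustive matching agree for K = 5", {
  x <- random_proportions(5, 10, seed = 31, labeled = FALSE)
  y <- permute_rows(x, c(3, 5, 1, 2, 4))
  exhaustive <- match_components(x, y, max_perms = 1000)
  sampled <- match_components(x, y, max_perms = 119, seed = 8)
  # the sampled mode may miss the optimum in principle, but for an exactly
  # permuted copy the exhaustive answer is the inverse permutation
  expect_equal(y$values[exhaustive, ], x$values)
  expect_length(sampled, 5)
})

test_that("average_proportions is the entrywise mean and stays stochastic", {
  a1 <- proportion_matrix(cbind(c(0.2, 0.8), c(0.5, 0.5)))
  a2 <- proportion_matrix(cbind(c(0.4, 0.6), c(0.1, 0.9)))
  avg <- average_proportions(a1, a2)
  expect_equal(avg$values, cbind(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(average_proportions(a1, a1)$values, a1$values)
  r1 <- random_proportions(4, 9, seed = 1)
  r2 <- random_proportions(4, 9, seed = 2)
  expect_true(all(abs(colSums(average_proportions(r1, r2)$values) - 1)
                  < 1e-12))
})

test_that("unknown method ids are rejected with the list of valid ones", {
  expect_error(method_spec("bogus"), "r_WNM")
  expect_error(method_spec("external"), "external_command")
  expect_identical(method_spec("m_MDC")$modality_use, "dnam")
})

test_that("every baseline emits a valid column-stochastic estimate", {
  ds <- small_benchmark(seed = 44, n_datasets = 1)[[1]]
  for (id in c("r_WIC", "r_WNM", "m_EDC", "m_MDC", "m_WIC", "b_WIC",
               "b_COM", "b_MEA", "ref_OLS", "ref_RLR")) {
    res <- run_baseline(light_spec(id), ds, k = 5, seed = 77)
    expect_s3_class(res$a_est, "proportion_matrix")
    expect_identical(res$method_id, id)
    expect_equal(nrow(res$a_est$values), 5)
    expect_true(all(abs(colSums(res$a_est$values) - 1) < 1e-8),
                label = paste(id, "column sums"))
    expect_identical(res$a_est$sample_ids, ds$d_rna$sample_ids)
  }
})

test_that("b_COM records the cross-omic warm start provenance", {
  ds <- small_benchmark(seed = 45, n_datasets = 1)[[1]]
  res <- run_baseline(light_spec("b_COM"), ds, k = 5, seed = 3)
  prov <- res$diagnostics$start_a_provenance
  expect_identical(prov$source, "r_WNM transcriptome estimate")
  expect_false(prov$prematched)
  expect_true(res$diagnostics$start_a_provided)
})

test_that("b_WIC equals its matched-then-averaged composition", {
  ds <- small_benchmark(seed = 46, n_datasets = 1)[[1]]
  spec <- light_spec("b_WIC")
  seed <- 9
  res <- run_baseline(spec, ds, k = 5, seed = seed)
  rna <- mixdecon:::run_rna_wic(ds, spec, 5, derive_seed(seed, "rna"))
  met <- mixdecon:::run_met_wic(ds, spec, 5, derive_seed(seed, "met"))
  p <- match_components(rna$a_est, met$a_est,
                        seed = derive_seed(seed, "match"))
  manual <- average_proportions(rna$a_est, permute_rows(met$a_est, p))
  expect_equal(res$a_est$values, manual$values, tolerance = 1e-12)
})

test_that("the external adapter runs, validates, and fails structurally", {
  ds <- small_benchmark(seed = 47, n_datasets = 1)[[1]]
  workroot <- withr::local_tempdir()
  truth_path <- file.path(workroot, "truth.tsv")
  write_proportion_matrix(ds$a_true, truth_path)

  tpl_ok <- paste("cp", truth_path, "{out} # {rna} {met} {k}")
  res <- run_baseline(method_spec("external", external_command = tpl_ok),
                      ds, k = 5, seed = 1)
  expect_equal(matched_mae(res$a_est, ds$a_true)$mae, 0, tolerance = 1e-9)

  # wrong component count
  bad <- permute_rows(ds$a_true, 1:5)
  bad$values <- bad$values[1:4, ]
  bad$values <- sweep(bad$values, 2, colSums(bad$values), "/")
  bad$row_labels <- bad$row_labels[1:4]
  bad_path <- file.path(workroot, "bad.tsv")
  write_proportion_matrix(bad, bad_path)
  expect_error(
    run_baseline(method_spec(
      "external",
      external_command = paste("cp", bad_path, "{out} # {rna} {met} {k}")),
      ds, k = 5, seed = 1),
    class = "mixdecon_external_failure")

  # near-stochastic columns renormalized with a warning
  off <- ds$a_true
  off$values <- off$values * 1.0005
  class(off) <- "proportion_matrix"
  off_path <- file.path(workroot, "off.tsv")
  mixdecon:::write_matrix_tsv(off$values, off$row_labels, off$sample_ids,
                              off_path, "cell_type")
  expect_warning(
    res2 <- run_baseline(method_spec(
      "external",
      external_command = paste("cp", off_path, "{out} # {rna} {met} {k}")),
      ds, k = 5, seed = 1),
    "renormalizing")
  expect_true(all(abs(colSums(res2$a_est$values) - 1) < 1e-10))

  # nonzero exit is a structured failure
  expect_error(
    run_baseline(method_spec(
      "external", external_command = "false # {rna} {met} {k} {out}"),
      ds, k = 5, seed = 1),
    class = "mixdecon_external_failure")

  # missing placeholders rejected up front
  expect_error(run_external_method("prog --rna {rna}", workroot, 5),
               "placeholder")
})
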