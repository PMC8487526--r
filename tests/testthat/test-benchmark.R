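# MAE scoring, matched scoring, the replicated benchmark protocol,
# leaderboard and report rendering.

test_that("mae follows the hand example and is symmetric", {
  a_true <- proportion_matrix(cbind(c(0.6, 0.4), c(0.2, 0.8)))
  a_est <- proportion_matrix(cbind(c(0.5, 0.5), c(0.3, 0.7)))
  expect_equal(mae(a_est, a_true), 0.1)
  expect_equal(mae(a_true, a_est), mae(a_est, a_true))
  expect_equal(mae(a_true, a_true), 0)
  expect_error(mae(a_true, random_proportions(3, 2)), "shape")
})

test_that("matched_mae minimizes over permutations and matches enumeration", {
  a <- random_proportions(4, 10, seed = 3)
  shuffled <- permute_rows(a, c(4, 1, 2, 3))
  sc <- matched_mae(shuffled, a)
  expect_equal(sc$mae, 0)
  expect_equal(shuffled$values[sc$permutation, ], a$values)

  for (i in 1:5) {
    x <- random_proportions(3, 7, seed = 300 + i, labeled = FALSE)
    y <- random_proportions(3, 7, seed = 400 + i)
    got <- matched_mae(x, y)
    vals <- vapply(enum_perms(3), function(p)
      mean(abs(x$values[p, ] - y$values)), numeric(1))
    expect_equal(got$mae, min(vals))
    expect_lte(got$mae, mae(x, y))
  }
  big <- random_proportions(9, 4, seed = 1)
  expect_error(matched_mae(big, big), "sampled")
  sc_big <- matched_mae(big, big, sampled = TRUE, max_perms = 200)
  expect_true(is.finite(sc_big$mae) && sc_big$mae >= 0)
  expect_identical(sort(sc_big$permutation), 1:9)
})

test_that("matched MAE of the uniform estimator equals its direct formula", {
  ds <- small_benchmark(seed = 50, n_datasets = 1)[[1]]
  K <- 5
  unif <- proportion_matrix(matrix(1 / K, K, 30),
                            row_labels = paste0("c", 1:K),
                            sample_ids = ds$a_true$sample_ids,
                            labeled = FALSE)
  sc <- matched_mae(unif, ds$a_true)
  expect_equal(sc$mae, mean(abs(ds$a_true$values - 1 / K)))
})

test_that("MAE is linear in the error scale", {
  a <- random_proportions(4, 10, seed = 9)
  set.seed(2)
  e <- matrix(rnorm(40), 4, 10)
  e <- sweep(e, 2, colMeans(e))            # column-sum-preserving error
  e <- e * 0.9 * min(a$values / (3 * abs(e) + 1e-12))  # keep a + 3e >= 0
  perturb <- function(c_scale) {
    v <- a$values + c_scale * e
    stopifnot(all(v >= 0))
    proportion_matrix(v, a$row_labels, a$sample_ids)
  }
  m1 <- mae(perturb(1), a)
  m3 <- mae(perturb(3), a)
  expect_equal(m3, 3 * m1, tolerance = 1e-10)
})

test_that("run_benchmark produces the full record grid deterministically", {
  sets <- small_benchmark(seed = 60, n_datasets = 2)
  methods <- list(light_spec("ref_OLS"), light_spec("m_WIC"))
  rep1 <- run_benchmark(methods, sets, n_runs = 2, root_seed = 5)
  expect_equal(nrow(rep1$records), 2 * 2 * 2)
  expect_true(all(rep1$records$status == "ok"))
  rep2 <- run_benchmark(methods, sets, n_runs = 2, root_seed = 5)
  cols <- setdiff(names(rep1$records), "elapsed_seconds")
  expect_identical(rep1$records[cols], rep2$records[cols])

  hidden <- sets[[1]]
  hidden$a_true <- NULL
  expect_error(run_benchmark(methods, list(hidden), 1, 1), "truth")
})

test_that("a failing method is recorded without aborting the sweep", {
  sets <- small_benchmark(seed = 61, n_datasets = 1)
  methods <- list(
    light_spec("ref_OLS"),
    method_spec("external",
                external_command = "false # {rna} {met} {k} {out}"))
  rep <- run_benchmark(methods, sets, n_runs = 1, root_seed = 2)
  expect_identical(rep$records$status,
                   c("ok", "failed"))
  expect_false(is.na(rep$records$error_message[2]))
  lb <- make_leaderboard(rep)
  expect_identical(lb$status, c("ok", "all_failed"))
  expect_identical(lb$method_id[2], "external")
})

test_that("leaderboard ranks by mean MAE with sd/id tie-breaks", {
  rec <- data.frame(
    record_id = paste0("r", 1:6),
    method_id = rep(c("mB", "mA", "mC"), each = 2),
    modality_use = "rna", dataset_index = 1, run_index = 1:2, run_seed = 1,
    matched_mae = c(0.05, 0.05, 0.02, 0.02, 0.05, 0.05),
    elapsed_seconds = 1, status = "ok", error_message = NA_character_)
  rec$matched_mae[5:6] <- c(0.04, 0.06)    # same mean as mB, larger sd
  report <- mixdecon:::new_score_report(
    rec, list(), mixdecon:::aggregate_records(rec), list())
  lb <- make_leaderboard(report)
  expect_identical(lb$method_id, c("mA", "mB", "mC"))
  expect_identical(lb$rank, 1:3)
  expect_equal(nrow(lb), 3)
})

test_that("score reports round-trip through JSON with aggregate checking", {
  sets <- small_benchmark(seed = 62, n_datasets = 1)
  rep <- run_benchmark(list(light_spec("ref_OLS")), sets, n_runs = 2,
                       root_seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_score_report(rep, path)
  back <- read_score_report(path)
  expect_equal(back$aggregates$mean_mae, rep$aggregates$mean_mae,
               tolerance = 1e-12)
  # tampered aggregates are detected
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$aggregates$mean_mae <- p$aggregates$mean_mae + 0.01
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(read_score_report(path), "do not match")
})

test_that("render_report writes figures and tables", {
  sets <- small_benchmark(seed = 63, n_datasets = 1)
  rep <- run_benchmark(list(light_spec("ref_OLS"), light_spec("m_WIC")),
                       sets, n_runs = 2, root_seed = 4)
  out <- withr::local_tempdir()
  render_report(rep, out)
  for (f in c("leaderboard.csv", "records.csv", "report.json",
              "figures/mae_boxplot.pdf", "figures/mae_boxplot.png",
              "figures/a_est_ref_OLS.pdf", "figures/abs_error_ref_OLS.png"))
    expect_gt(file.size(file.path(out, f)), 0)
  det <- rep$details[[rep$records$record_id[1]]]
  expect_equal(dim(det$a_est_matched), c(5, 30))
  empty <- mixdecon:::new_score_report(
    rep$records[rep$records$status == "failed", ], list(),
    data.frame(), list())
  expect_error(render_report(empty, out))
})
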