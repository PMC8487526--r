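# Constrained least-squares primitives, NMF variants, weighted-ICA
# deconvolution, and reference-based regression.

test_that("simplex_lsq matches the brute-force grid and its constraints", {
  expect_equal(simplex_lsq(diag(2), c(0.3, 0.7)), c(0.3, 0.7),
               tolerance = 1e-10)
  expect_equal(simplex_lsq(diag(2), c(1.5, 0)), c(1, 0), tolerance = 1e-10)
  set.seed(101)
  xs <- seq(0, 1, by = 1e-4)
  for (i in 1:100) {
    t <- matrix(rnorm(6), 3, 2)
    d <- rnorm(3)
    a <- simplex_lsq(t, d)
    expect_lt(abs(sum(a) - 1), 1e-10)
    expect_gte(min(a), -1e-12)
    obj <- colSums((d - t %*% rbind(xs, 1 - xs))^2)
    best <- xs[which.min(obj)]
    expect_lt(sqrt(sum((a - c(best, 1 - best))^2)), 2e-4)
  }
})

test_that("box_lsq matches grid search and ordinary least squares", {
  set.seed(202)
  for (i in 1:100) {
    a <- matrix(rnorm(6), 2, 3)
    d <- rnorm(3) * 2
    x <- box_lsq(a, d, 0, 1)
    expect_true(all(x >= -1e-12 & x <= 1 + 1e-12))
    expect_lt(sqrt(sum((x - box_grid_oracle(a, d))^2)), 2e-4)
  }
  # interior optimum equals OLS
  a <- matrix(c(1, 0.2, 0.1, 1, 0.4, 0.9), 2, 3)
  truth <- c(0.4, 0.6)
  d <- as.numeric(t(a) %*% truth)
  expect_equal(box_lsq(a, d, 0, 1), truth, tolerance = 1e-9)
  expect_equal(box_lsq(a, d, 0, Inf), truth, tolerance = 1e-9)
})

test_that("all NMF variants recover noiseless marker-structured mixtures", {
  for (seed in 1:5) {
    fx <- marker_recovery_fixture(K = 3, m = 200, n = 20, seed = seed)
    cfg <- nmf_config(k = 3, seed = seed)
    r_sp <- sparse_nmf(fx$d_rna, cfg)
    r_cn <- constrained_nmf(fx$d_met, cfg)
    r_rg <- regularized_constrained_nmf(fx$d_met, cfg)
    expect_lt(matched_mae(r_sp$a_est, fx$a_true)$mae, 0.01)
    sc <- matched_mae(r_cn$a_est, fx$a_true)$mae
    expect_lt(sc, 0.01)
    expect_lt(matched_mae(r_rg$a_est, fx$a_true)$mae, 0.01)
    for (r in list(r_sp, r_cn, r_rg))
      expect_true(all(diff(r$diagnostics$objective_trace) <= 1e-9))
  }
})

test_that("constrained_nmf also recovers the reference profiles", {
  fx <- marker_recovery_fixture(K = 3, m = 200, n = 20, seed = 3)
  r <- constrained_nmf(fx$d_met, nmf_config(k = 3, seed = 3))
  p <- matched_mae(r$a_est, fx$a_true)$permutation
  expect_lt(max(abs(r$t_est_met$values[, p] - fx$T)), 0.05)
  # iterates satisfy the constraint sets
  expect_true(all(r$t_est_met$values >= 0 & r$t_est_met$values <= 1))
  expect_true(all(abs(colSums(r$a_est$values) - 1) < 1e-8))
})

test_that("NMF preconditions and reproducibility hold", {
  fx <- marker_recovery_fixture(seed = 8)
  neg <- fx$d_met
  neg$values[1, 1] <- -0.1          # bypass constructor to probe the guard
  expect_error(sparse_nmf(neg, nmf_config(k = 3)), "non-negative")
  expect_error(constrained_nmf(fx$d_rna, nmf_config(k = 3)), "\\[0, 1\\]")
  r1 <- sparse_nmf(fx$d_rna, nmf_config(k = 3, seed = 5, n_init = 2,
                                        max_iter = 60))
  r2 <- sparse_nmf(fx$d_rna, nmf_config(k = 3, seed = 5, n_init = 2,
                                        max_iter = 60))
  expect_identical(r1$a_est$values, r2$a_est$values)
})

test_that("NMF A-estimates are equivariant to feature permutation", {
  fx <- marker_recovery_fixture(seed = 12)
  set.seed(4)
  p <- sample(200)
  dp <- omic_matrix(fx$d_met$values[p, ], "meth_beta",
                    paste0("f", 1:200)[p], fx$d_met$sample_ids)
  cfg <- nmf_config(k = 3, seed = 7, n_init = 2, max_iter = 80)
  r <- constrained_nmf(fx$d_met, cfg)
  rp <- constrained_nmf(dp, cfg)
  expect_equal(r$a_est$values, rp$a_est$values, tolerance = 1e-9)
})

test_that("the 0/1 regularizer pulls profile estimates toward binary values", {
  set.seed(55)
  K <- 3; m <- 150; n <- 25
  Tm <- matrix(sample(c(0.05, 0.95), m * K, replace = TRUE), m, K)
  g <- matrix(rgamma(K * n, 1), K)
  A <- cbind(sweep(g[, 1:(n - K)], 2, colSums(g[, 1:(n - K)]), "/"),
             diag(K) * 0.96 + 0.04 / K)
  A <- sweep(A, 2, colSums(A), "/")
  D <- pmin(pmax(Tm %*% A + matrix(rnorm(m * n, 0, 0.03), m), 0), 1)
  d <- omic_matrix(D, "meth_beta", paste0("f", 1:m), paste0("s", 1:n))
  cfg0 <- nmf_config(k = K, seed = 2, lambda = 0)
  cfg1 <- nmf_config(k = K, seed = 2, lambda = 0.01)
  t0 <- regularized_constrained_nmf(d, cfg0)$t_est_met$values
  t1 <- regularized_constrained_nmf(d, cfg1)$t_est_met$values
  binariness <- function(x) mean(abs(x - round(x)))
  expect_lte(binariness(t1), binariness(t0))
})

test_that("lambda = 0 reduces the regularized variant to constrained_nmf", {
  fx <- marker_recovery_fixture(seed = 19)
  cfg <- nmf_config(k = 3, seed = 4, lambda = 0, n_init = 2, max_iter = 100)
  r0 <- constrained_nmf(fx$d_met, cfg)
  r1 <- regularized_constrained_nmf(fx$d_met, cfg)
  expect_equal(r0$a_est$values, r1$a_est$values, tolerance = 1e-8)
})

test_that("a warm start from the true proportions speeds up convergence", {
  iters_warm <- iters_cold <- maes <- numeric(5)
  for (s in 1:5) {
    fx <- marker_recovery_fixture(K = 3, seed = 30 + s)
    warm_cfg <- nmf_config(k = 3, seed = s, n_init = 1,
                           start_a = fx$a_true)
    warm <- regularized_constrained_nmf(fx$d_met, warm_cfg)
    ids <- warm$diagnostics$init_ids
    expect_true("start_a" %in% ids)
    maes[s] <- matched_mae(warm$a_est, fx$a_true)$mae
    by_init <- warm$diagnostics$n_iterations_by_init
    iters_warm[s] <- by_init[ids == "start_a"]
    iters_cold[s] <- by_init[ids == "random1"]
  }
  expect_true(all(maes < 0.005))
  expect_lt(median(iters_warm), median(iters_cold))
})

test_that("weighted component scores match a hand computation", {
  # 4 features, 2 components, 2 samples
  S <- cbind(c(5, 3, 0.1, 0), c(0, 0.2, 4, 2))
  vals <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  ws <- mixdecon:::weighted_component_scores(S, vals, n_top = 2)
  expect_equal(ws$scores[1, ], c(5 * 1 + 3 * 3, 5 * 2 + 3 * 4) / 8)
  expect_equal(ws$scores[2, ], c(4 * 5 + 2 * 7, 4 * 6 + 2 * 8) / 6)
  expect_identical(ws$top_sets[[1]], c(1L, 2L))
})

test_that("weighted-ICA proportions are stochastic and recover mixtures", {
  maes <- numeric(5)
  for (s in 1:5) {
    ds <- simulate_benchmark(
      simulation_config(seed = 40 + s, n_datasets = 1))[[1]]
    r <- ica_weighted_proportions(ds$d_rna, ica_decon_config(seed = s))
    expect_true(all(abs(colSums(r$a_est$values) - 1) < 1e-10))
    maes[s] <- matched_mae(r$a_est, ds$a_true)$mae
  }
  expect_lte(mean(maes), 0.15)
})

test_that("reference regression recovers exactly without noise and resists outliers", {
  fx <- marker_recovery_fixture(K = 3, m = 150, n = 15, seed = 61)
  r <- reference_regression(fx$d_rna, fx$t_rna, "ols")
  expect_true(r$a_est$labeled)
  expect_lt(mae(r$a_est, fx$a_true), 1e-8)
  expect_true(all(abs(colSums(r$a_est$values) - 1) < 1e-12))

  ols_mae <- rlr_mae <- numeric(10)
  for (s in 1:10) {
    fx <- marker_recovery_fixture(K = 3, m = 150, n = 15, seed = 70 + s)
    set.seed(s)
    vals <- fx$d_rna$values
    out_rows <- sample(150, 8)           # ~5% gross outlier features
    vals[out_rows, ] <- vals[out_rows, ] + 15
    dd <- omic_matrix(vals, "rna_log2", fx$d_rna$feature_ids,
                      fx$d_rna$sample_ids)
    ols_mae[s] <- mae(reference_regression(dd, fx$t_rna, "ols")$a_est,
                      fx$a_true)
    rlr_mae[s] <- mae(reference_regression(dd, fx$t_rna, "rlr")$a_est,
                      fx$a_true)
  }
  expect_lte(median(rlr_mae), median(ols_mae))
  small <- reference_profiles(fx$t_rna$values[1:2, ], "rna_log2",
                              fx$t_rna$feature_ids[1:2],
                              fx$t_rna$cell_type_labels)
  expect_error(reference_regression(fx$d_rna, small, "ols"),
               "fewer common features")
})
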