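# Programmatic fixtures shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Small random omic matrix for I/O round-trips.
random_omic <- function(m = 10, n = 4, modality = "meth_beta", seed = 1) {
  set.seed(seed)
  v <- matrix(runif(m * n), m, n)
  if (modality == "rna_log2") v <- v * 10
  omic_matrix(v, modality, feature_ids = sprintf("f%03d", seq_len(m)),
              sample_ids = sprintf("s%02d", seq_len(n)))
}

random_proportions <- function(K = 3, n = 5, seed = 1, labeled = TRUE) {
  set.seed(seed)
  g <- matrix(rgamma(K * n, 1), K)
  proportion_matrix(sweep(g, 2, colSums(g), "/"),
                    row_labels = paste0("ct", seq_len(K)),
                    sample_ids = paste0("s", seq_len(n)), labeled = labeled)
}

# Noiseless, identifiable marker-structured instance: each cell type owns an
# exclusive marker block (zero in the other types), plus shared background
# rows, and the mixture includes one near-pure sample per cell type so the
# factorization is pinned (no feasible mixing of components fits the data).
marker_recovery_fixture <- function(K = 3, m = 200, n = 20, seed = 1,
                                    markers_per_type = 30,
                                    rna_scale = 8) {
  set.seed(seed)
  Tm <- matrix(rep(runif(m, 0.1, 0.5), K), m, K)
  for (k in seq_len(K)) {
    rows <- ((k - 1) * markers_per_type + 1):(k * markers_per_type)
    Tm[rows, ] <- 0
    Tm[rows, k] <- runif(markers_per_type, 0.7, 0.95)
  }
  n_free <- n - K
  g <- matrix(rgamma(K * n_free, 1), K)
  A <- cbind(sweep(g, 2, colSums(g), "/"),
             diag(K) * 0.97 + (1 - 0.97) / K)  # near-pure anchor samples
  A <- sweep(A, 2, colSums(A), "/")
  D <- Tm %*% A
  sample_ids <- paste0("s", seq_len(n))
  list(
    T = Tm, A = A, D = D,
    d_met = omic_matrix(D, "meth_beta", paste0("f", seq_len(m)), sample_ids),
    d_rna = omic_matrix(D * rna_scale, "rna_log2", paste0("f", seq_len(m)),
                        sample_ids),
    t_met = reference_profiles(Tm, "meth_beta", paste0("f", seq_len(m)),
                               paste0("ct", seq_len(K))),
    t_rna = reference_profiles(Tm * rna_scale, "rna_log2",
                               paste0("f", seq_len(m)),
                               paste0("ct", seq_len(K))),
    a_true = proportion_matrix(A, paste0("ct", seq_len(K)), sample_ids))
}

# Desk-scale paired benchmark dataset (small feature dimensions) for pipeline
# tests that don't need the full default sizes.
small_benchmark <- function(seed = 5, n_datasets = 2) {
  scfg <- simulation_config(seed = seed, n_genes = 600, n_probes = 800,
                            n_datasets = n_datasets)
  pcfg <- profile_config(n_markers_per_type = 30)
  simulate_benchmark(scfg, pcfg)
}

# Lightweight method specs for sweep tests (fewer ICA runs, smaller filter).
light_spec <- function(id) {
  method_spec(id,
              ica_sel = ica_selection_config(n_runs = 12),
              nmf = nmf_config(n_init = 2, max_iter = 200),
              n_var_probes = 300)
}

# Independent permutation enumeration (recursive; avoids reusing the
# package's own machinery in oracle comparisons).
enum_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    for (p in enum_perms(k - 1))
      out[[length(out) + 1]] <- c(i, rest[p])
  }
  out
}

# coarse-to-fine grid oracle for the 2-D box problem (convex, so refining
# around the coarse optimum reaches the global one at step 1e-4)
box_grid_oracle <- function(a, d, lower = 0, upper = 1) {
  lo <- c(lower, lower); hi <- c(upper, upper); step <- 1e-2
  best <- NULL
  for (r in 1:3) {
    g <- as.matrix(expand.grid(seq(lo[1], hi[1], step),
                               seq(lo[2], hi[2], step)))
    vals <- colSums((d - t(a) %*% t(g))^2)
    best <- g[which.min(vals), ]
    lo <- pmax(best - 2 * step, lower)
    hi <- pmin(best + 2 * step, upper)
    step <- step / 10
  }
  unname(best)
}

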