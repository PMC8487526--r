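# NMF-style deconvolution: alternating constrained least squares on T and A.
# Three variants share the loop:
#   sparse_nmf                 — T, A >= 0, L1 penalty on A (transcriptome)
#   constrained_nmf            — 0 <= T <= 1, A columns on the simplex
#   regularized_constrained_nmf — adds lambda * sum(T (1 - T)), pushing
#                                 methylation profile estimates toward 0/1

#' Configuration for the NMF deconvolution variants
#'
#' @param k number of components (cell types) to extract.
#' @param max_iter maximum alternating iterations per initialization
#'   (default 500).
#' @param tol stop when the relative objective decrease falls below this
#'   (default 1e-6).
#' @param n_init number of random initializations; the best final objective
#'   wins (default 5).
#' @param sparsity L1 penalty weight on `A` (sparse variant only,
#'   default 0.1).
#' @param ridge optional L2 penalty on `T` in the sparse variant (default 0).
#'   A small ridge removes the scale indeterminacy between the factors, but
#'   it also biases the fit toward mixed components, so it is off by default
#'   (the final column normalization of `A` fixes the scale instead).
#' @param lambda weight of the `sum(T (1 - T))` regularizer pulling estimated
#'   methylation values toward 0 or 1 (regularized variant only,
#'   default 0.01).
#' @param start_a optional [proportion_matrix] used as one additional
#'   initialization (warm start, e.g. from a transcriptome fit).
#' @param seed RNG seed for the initializations.
#' @return an `nmf_config` list.
#' @export
nmf_config <- function(k = 5, max_iter = 500, tol = 1e-6, n_init = 5,
                       sparsity = 0.1, ridge = 0, lambda = 0.01,
                       start_a = NULL, seed = 1L) {
  stopifnot(k >= 2, max_iter >= 1, tol > 0, n_init >= 1, sparsity >= 0,
            ridge >= 0, lambda >= 0)
  if (!is.null(start_a)) stopifnot(inherits(start_a, "proportion_matrix"))
  structure(list(k = k, max_iter = max_iter, tol = tol, n_init = n_init,
                 sparsity = sparsity, ridge = ridge, lambda = lambda,
                 start_a = start_a, seed = as.integer(seed)),
            class = "nmf_config")
}

# Shared alternating loop. `variant` selects the constraint set/penalty.
# Returns list(T, A, trace, n_iter, objective).
anls_fit <- function(D, K, A0, variant, cfg) {
  n <- ncol(D)
  A <- A0
  Tm <- matrix(0, nrow(D), K)
  obj <- Inf
  trace <- numeric(0)
  lambda <- if (variant == "regularized") cfg$lambda else 0
  sparsity <- if (variant == "sparse") cfg$sparsity else 0
  ridge <- if (variant == "sparse") cfg$ridge else 0
  upperT <- if (variant == "sparse") Inf else 1
  for (it in seq_len(cfg$max_iter)) {
    ## T update: rows share the Hessian A A' (minus lambda I when regularized,
    ## plus the stabilizing ridge for the sparse variant)
    Qt <- tcrossprod(A)
    if (ridge > 0) Qt <- Qt + diag(ridge, K)
    if (lambda > 0) Qt <- Qt - diag(lambda, K)
    if (any(diag(Qt) <= 0))
      stop("regularizer dominates the quadratic term; reduce lambda",
           call. = FALSE)
    Ct <- -tcrossprod(D, A)
    if (lambda > 0) Ct <- Ct + lambda / 2
    Tm <- cd_box_rows(Tm, Qt, Ct, lower = 0, upper = upperT,
                      max_sweep = 30L)
    ## A update given T
    Qa <- crossprod(Tm)
    TtD <- crossprod(Tm, D)
    if (variant == "sparse") {
      Ca <- -t(TtD) + sparsity / 2
      A <- t(cd_box_rows(t(A), Qa, Ca, lower = 0, upper = Inf,
                         max_sweep = 30L))
    } else {
      A <- .simplex_cols_cpp(Qa, TtD)
    }
    resid <- D - Tm %*% A
    cur <- sum(resid^2) + sparsity * sum(A) + ridge * sum(Tm^2) +
      lambda * sum(Tm * (1 - Tm))
    trace <- c(trace, cur)
    if (is.finite(obj) && (obj - cur) / max(obj, .Machine$double.eps) < cfg$tol)
      { obj <- cur; break }
    obj <- cur
  }
  list(T = Tm, A = A, trace = trace, n_iter = length(trace), objective = obj)
}

random_a_init <- function(K, n) {
  g <- matrix(stats::rgamma(K * n, 1), K)
  sweep(g, 2, colSums(g), "/")
}

run_nmf_variant <- function(d, cfg, variant, method_label) {
  stopifnot(inherits(d, "omic_matrix"), inherits(cfg, "nmf_config"))
  D <- d$values
  if (variant == "sparse") {
    if (min(D) < 0) stop("sparse_nmf requires non-negative input", call. = FALSE)
  } else if (min(D) < 0 || max(D) > 1) {
    stop(method_label, " requires input in [0, 1]", call. = FALSE)
  }
  K <- cfg$k
  n <- ncol(D)
  inits <- lapply(seq_len(cfg$n_init), function(i)
    list(id = paste0("random", i),
         A0 = with_seed(derive_seed(cfg$seed, "init", i),
                        random_a_init(K, n))))
  if (!is.null(cfg$start_a)) {
    if (nrow(cfg$start_a$values) != K || ncol(cfg$start_a$values) != n)
      stop("start_a has the wrong shape for this problem", call. = FALSE)
    inits <- c(inits, list(list(id = "start_a", A0 = cfg$start_a$values)))
  }
  t0 <- proc.time()[["elapsed"]]
  fits <- lapply(inits, function(ini) anls_fit(D, K, ini$A0, variant, cfg))
  best <- which.min(vapply(fits, `[[`, numeric(1), "objective"))
  fit <- fits[[best]]
  Tm <- fit$T; A <- fit$A
  if (variant == "sparse") {
    ## Per-component scales are indeterminate in an unconstrained nonneg
    ## factorization (c T_k, A_k / c fit identically). Pin them with the
    ## physical constraint that true proportions sum to one per sample:
    ## s = argmin_{s >= 0} sum_n (1 - s' A_.n)^2, rescale component k by
    ## s_k (T_k inversely), then normalize columns exactly.
    s <- qp_box(tcrossprod(A), -as.numeric(A %*% rep(1, n)), 0, Inf)
    A <- A * s
    Tm <- sweep(Tm, 2, pmax(s, .Machine$double.eps), "/")
    cs <- colSums(A)
    if (any(cs <= 0)) {
      warning("empty proportion column(s); replaced by uniform", call. = FALSE)
      A[, cs <= 0] <- 1 / K
      cs <- colSums(A)
    }
    A <- sweep(A, 2, cs, "/")
  }
  a_est <- proportion_matrix(A, row_labels = paste0("comp", seq_len(K)),
                             sample_ids = d$sample_ids, labeled = FALSE)
  t_est <- tryCatch(
    reference_profiles(if (variant == "sparse") pmax(Tm, 0) else
                         pmin(pmax(Tm, 0), 1),
                       d$modality, feature_ids = d$feature_ids,
                       cell_type_labels = paste0("comp", seq_len(K))),
    error = function(e) NULL)
  deconvolution_result(
    a_est, method_id = method_label, run_seed = cfg$seed,
    t_est_rna = if (d$modality == "rna_log2") t_est else NULL,
    t_est_met = if (d$modality == "meth_beta") t_est else NULL,
    elapsed_seconds = proc.time()[["elapsed"]] - t0,
    diagnostics = list(
      objective_trace = fit$trace, n_iterations = fit$n_iter,
      init_used = inits[[best]]$id, variant = variant,
      objectives_by_init = vapply(fits, `[[`, numeric(1), "objective"),
      n_iterations_by_init = vapply(fits, `[[`, numeric(1), "n_iter"),
      init_ids = vapply(inits, `[[`, character(1), "id"),
      start_a_provided = !is.null(cfg$start_a)))
}

#' Sparse NMF deconvolution
#'
#' Alternating non-negativity-constrained least squares minimizing
#' `||D - T A||_F^2 + sparsity * sum(A)`; both factors non-negative, L1
#' penalty sparsifying the proportion factor. The best of `n_init` random
#' initializations (by final objective) is kept. Because per-component
#' scales are indeterminate in an unconstrained non-negative factorization,
#' each component is then rescaled by the non-negative least-squares
#' solution of `1 ~ A` (the scale under which estimated proportions best sum
#' to one per sample, `T` rescaled inversely), and `A` columns are finally
#' normalized to sum to 1 exactly.
#'
#' @param d a non-negative [omic_matrix] (log2 expression).
#' @param cfg an [nmf_config()].
#' @return a [deconvolution_result] with anonymous components; diagnostics
#'   carry the objective trace, iteration count and winning initialization.
#' @export
sparse_nmf <- function(d, cfg = nmf_config()) {
  run_nmf_variant(d, cfg, "sparse", "sparse_nmf")
}

#' Constrained NMF deconvolution for beta-values
#'
#' Minimizes `||D - T A||_F^2` under the methylation constraints
#' `0 <= T <= 1` and column-stochastic `A` (each sample's proportions
#' non-negative, summing to 1), alternating exact box-constrained updates of
#' `T` rows and simplex-constrained updates of `A` columns.
#'
#' @param d an [omic_matrix] with entries in `[0, 1]`.
#' @param cfg an [nmf_config()].
#' @return a [deconvolution_result].
#' @export
constrained_nmf <- function(d, cfg = nmf_config()) {
  run_nmf_variant(d, cfg, "constrained", "constrained_nmf")
}

#' Regularized constrained NMF deconvolution for beta-values
#'
#' As [constrained_nmf()] with the additional penalty
#' `lambda * sum(T * (1 - T))`, which favors estimated methylation profiles
#' near 0 or 1 — the biologically expected near-binary methylation state of a
#' pure cell population. If `cfg$start_a` is provided it is used as one extra
#' initialization (a cross-omic warm start) and recorded in the diagnostics.
#'
#' @param d an [omic_matrix] with entries in `[0, 1]`.
#' @param cfg an [nmf_config()]; `lambda` defaults to 0.01.
#' @return a [deconvolution_result].
#' @export
regularized_constrained_nmf <- function(d, cfg = nmf_config()) {
  run_nmf_variant(d, cfg, "regularized", "regularized_constrained_nmf")
}
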