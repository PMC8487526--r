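# Scoring: mean absolute error on proportion matrices, its minimum over
# component relabelings (matched MAE), and correlation-based component
# matching used by the multi-omic averaging strategies.

#' Mean absolute error between two proportion matrices
#'
#' `MAE = sum(|A_est - A_true|) / (N K)` — the benchmark's discriminating
#' metric, averaged over all cells of the K x N proportion matrices. Requires
#' identical shape and row/column order (use [matched_mae()] for anonymous
#' components).
#'
#' @param a_est,a_true [proportion_matrix] objects of identical shape.
#' @return a scalar in `[0, 2]`.
#' @export
#' @examples
#' a1 <- proportion_matrix(matrix(c(.6, .4, .2, .8), 2))
#' a2 <- proportion_matrix(matrix(c(.5, .5, .3, .7), 2))
#' mae(a1, a2)  # 0.1
mae <- function(a_est, a_true) {
  stopifnot(inherits(a_est, "proportion_matrix"),
            inherits(a_true, "proportion_matrix"))
  if (!all(dim(a_est$values) == dim(a_true$values)))
    stop("proportion matrices must have identical shape", call. = FALSE)
  mean(abs(a_est$values - a_true$values))
}

# All permutations of 1..k in lexicographic row order.
perms_lex <- function(k) {
  p <- pracma::perms(seq_len(k))
  p[do.call(order, as.data.frame(p)), , drop = FALSE]
}

#' Permutation-matched mean absolute error
#'
#' Reference-free methods return anonymous components: before scoring, the
#' estimated rows must be assigned to true cell types. `matched_mae` returns
#' the minimum of [mae()] over all `K!` row permutations of `a_est`
#' (exhaustive for `K <= 8`; ties broken by the lexicographically smallest
#' permutation), together with the minimizing permutation.
#'
#' @param a_est,a_true [proportion_matrix] objects of equal shape.
#' @param sampled for `K > 8`, sample permutations instead of enumerating.
#' @param max_perms number of sampled permutations in sampled mode.
#' @param seed seed for sampled mode.
#' @return list with `mae` (scalar) and `permutation` (integer K-vector `p`
#'   such that `a_est$values[p, ]` aligns with `a_true`).
#' @export
matched_mae <- function(a_est, a_true, sampled = FALSE, max_perms = 10000,
                        seed = 1L) {
  stopifnot(inherits(a_est, "proportion_matrix"),
            inherits(a_true, "proportion_matrix"))
  if (!all(dim(a_est$values) == dim(a_true$values)))
    stop("proportion matrices must have identical shape", call. = FALSE)
  K <- nrow(a_est$values)
  if (K > 8 && !sampled)
    stop("K > 8: exhaustive matching infeasible; set sampled = TRUE for ",
         "approximate matching", call. = FALSE)
  E <- a_est$values; Tr <- a_true$values
  nk <- length(Tr)
  if (!sampled) {
    pm <- perms_lex(K)
  } else {
    pm <- with_seed(seed, t(replicate(max_perms, sample.int(K))))
  }
  best <- Inf; best_p <- seq_len(K)
  for (i in seq_len(nrow(pm))) {
    p <- pm[i, ]
    v <- sum(abs(E[p, , drop = FALSE] - Tr)) / nk
    if (v < best) { best <- v; best_p <- p }
  }
  list(mae = best, permutation = best_p)
}

#' Match anonymous components between two proportion matrices
#'
#' Returns the row permutation of `a_other` maximizing the Pearson
#' correlation between the vectorized `a_ref` and the row-permuted
#' `a_other` — the alignment step before averaging proportion estimates from
#' two omics. The search is exhaustive over all `K!` permutations whenever
#' `K! <= max_perms` (for K = 5, the 120 permutations are a superset of
#' anything a fixed number of random reorderings could visit); otherwise
#' `max_perms` uniformly sampled permutations are tried (seeded).
#'
#' @param a_ref,a_other [proportion_matrix] objects of equal shape and sample
#'   order.
#' @param max_perms exhaustive-search budget (default 1000).
#' @param seed seed for sampled mode.
#' @return integer K-vector `p` such that `a_other$values[p, ]` best
#'   correlates with `a_ref$values`.
#' @export
match_components <- function(a_ref, a_other, max_perms = 1000, seed = 1L) {
  stopifnot(inherits(a_ref, "proportion_matrix"),
            inherits(a_other, "proportion_matrix"))
  if (!all(dim(a_ref$values) == dim(a_other$values)))
    stop("proportion matrices must have identical shape", call. = FALSE)
  if (!identical(a_ref$sample_ids, a_other$sample_ids))
    stop("sample ids must match in order", call. = FALSE)
  K <- nrow(a_ref$values)
  exhaustive <- factorial(K) <= max_perms
  pm <- if (exhaustive) perms_lex(K)
  else with_seed(seed, t(replicate(max_perms, sample.int(K))))
  ref <- as.numeric(a_ref$values)
  best <- -Inf; best_p <- seq_len(K)
  for (i in seq_len(nrow(pm))) {
    p <- pm[i, ]
    v <- suppressWarnings(
      stats::cor(ref, as.numeric(a_other$values[p, , drop = FALSE])))
    if (is.finite(v) && v > best) { best <- v; best_p <- p }
  }
  best_p
}

#' Average two matched proportion matrices
#'
#' Entrywise mean of two aligned proportion matrices — the multi-omic
#' integration step. Convexity keeps the result column-stochastic.
#'
#' @param a1,a2 [proportion_matrix] objects of equal shape and sample order
#'   (align `a2` first with [match_components()]).
#' @return a [proportion_matrix].
#' @export
average_proportions <- function(a1, a2) {
  stopifnot(inherits(a1, "proportion_matrix"),
            inherits(a2, "proportion_matrix"))
  if (!all(dim(a1$values) == dim(a2$values)))
    stop("proportion matrices must have identical shape", call. = FALSE)
  if (!identical(a1$sample_ids, a2$sample_ids))
    stop("sample ids must match in order", call. = FALSE)
  proportion_matrix((a1$values + a2$values) / 2, row_labels = a1$row_labels,
                    sample_ids = a1$sample_ids,
                    labeled = a1$labeled && a2$labeled)
}

#' Reorder the rows of a proportion matrix
#'
#' @param a a [proportion_matrix].
#' @param p integer permutation of its rows.
#' @return the permuted [proportion_matrix].
#' @export
permute_rows <- function(a, p) {
  stopifnot(inherits(a, "proportion_matrix"),
            identical(sort(as.integer(p)), seq_len(nrow(a$values))))
  proportion_matrix(a$values[p, , drop = FALSE],
                    row_labels = a$row_labels[p], sample_ids = a$sample_ids,
                    labeled = a$labeled)
}
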