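# Weighted-ICA deconvolution: fixed-point ICA on the bulk matrix, component
# abundances scored per sample as the loading-weighted mean of each
# component's top features, then stacked into column-stochastic proportions.

#' Configuration for weighted-ICA deconvolution
#'
#' @param k number of independent components (cell types, default 5).
#' @param n_top number of top-loading features whose weighted mean gives the
#'   component's per-sample score (default 30).
#' @param seed RNG seed.
#' @return an `ica_decon_config` list.
#' @export
ica_decon_config <- function(k = 5, n_top = 30, seed = 1L) {
  stopifnot(k >= 2, n_top >= 1)
  structure(list(k = k, n_top = n_top, seed = as.integer(seed)),
            class = "ica_decon_config")
}

# Component abundance scores: for each loading column, the loading-weighted
# mean of the n_top top-loading features' values in each sample.
weighted_component_scores <- function(S, values, n_top) {
  k <- ncol(S)
  scores <- matrix(0, k, ncol(values))
  top_sets <- vector("list", k)
  for (j in seq_len(k)) {
    top <- order(-S[, j])[seq_len(min(n_top, nrow(S)))]
    top_sets[[j]] <- top
    w <- S[top, j]
    scores[j, ] <- as.numeric(w %*% values[top, , drop = FALSE]) / sum(w)
  }
  list(scores = scores, top_sets = top_sets)
}

#' Weighted-ICA estimation of cell-type proportions
#'
#' Runs whitened fixed-point ICA with `k` components on the bulk matrix,
#' orients each component so its feature-loading distribution is positively
#' skewed (marker-driven components then rank their defining features on
#' top), and scores component abundance in sample `n` as the loading-weighted
#' mean of the component's `n_top` top features:
#' `score_n = sum(w_g d_gn) / sum(w_g)` with `w_g` the loadings. Negative
#' scores are clamped to 0 and each sample's scores are normalized to sum to
#' 1 ("stacked" proportions); an all-zero column falls back to uniform `1/k`
#' with a warning. A non-convergent ICA run is retried with a fresh seed up
#' to 3 times.
#'
#' @param d an [omic_matrix] with more samples than `k`.
#' @param cfg an [ica_decon_config()].
#' @return a [deconvolution_result] with anonymous components.
#' @export
ica_weighted_proportions <- function(d, cfg = ica_decon_config()) {
  stopifnot(inherits(d, "omic_matrix"), inherits(cfg, "ica_decon_config"))
  if (ncol(d$values) <= cfg$k)
    stop("need n_samples > k for ICA", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  wh <- whiten_samples(d$values, cfg$k)
  fit <- NULL
  for (attempt in 1:3) {
    cand <- with_seed(derive_seed(cfg$seed, "ica-decon", attempt),
                      fastica_core(wh$z))
    if (cand$converged) { fit <- cand; break }
  }
  if (is.null(fit))
    stop("ICA failed to converge in 3 attempts", call. = FALSE)
  S <- orient_by_skewness(fit$S)
  ws <- weighted_component_scores(S, d$values, cfg$n_top)
  scores <- ws$scores
  top_sets <- ws$top_sets
  scores[scores < 0] <- 0
  cs <- colSums(scores)
  if (any(cs == 0)) {
    warning("all-zero component scores in some sample(s); using uniform 1/k",
            call. = FALSE)
    scores[, cs == 0] <- 1 / cfg$k
    cs <- colSums(scores)
  }
  a <- sweep(scores, 2, cs, "/")
  deconvolution_result(
    proportion_matrix(a, row_labels = paste0("comp", seq_len(cfg$k)),
                      sample_ids = d$sample_ids, labeled = FALSE),
    method_id = "ica_weighted_proportions", run_seed = cfg$seed,
    elapsed_seconds = proc.time()[["elapsed"]] - t0,
    diagnostics = list(n_iterations = fit$n_iter, attempts = attempt,
                       converged = TRUE,
                       top_features = lapply(top_sets, function(i)
                         d$feature_ids[i])))
}
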