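# Dimensionality-reduction steps used by the baseline pipelines: the
# most-variable-probe filter and stability-filtered ICA gene selection.

#' Configuration for ICA-stability gene selection
#'
#' @param n_components number of independent components per run (default 10).
#' @param n_runs number of repeated ICA runs with distinct seeds (default 50).
#' @param stability_threshold keep components whose average absolute
#'   correlation to their aligned partners across runs exceeds this
#'   (default 0.8).
#' @param fdr_q Benjamini-Hochberg q-value cutoff for top-contributing
#'   features within a stable component (default 0.2).
#' @param keep_duplicates keep a feature once per stable component it
#'   contributes to (`TRUE`), or deduplicate the union (`FALSE`).
#' @param optimal_alignment align components across runs by exhaustive
#'   assignment instead of the default greedy matching (small `n_components`
#'   only; the difference is negligible at the default settings).
#' @param seed RNG seed.
#' @return an `ica_selection_config` list.
#' @export
ica_selection_config <- function(n_components = 10, n_runs = 50,
                                 stability_threshold = 0.8, fdr_q = 0.2,
                                 keep_duplicates = FALSE,
                                 optimal_alignment = FALSE, seed = 1L) {
  stopifnot(n_components >= 2, n_runs >= 2,
            stability_threshold >= 0, stability_threshold <= 1,
            fdr_q > 0, fdr_q < 1)
  structure(list(n_components = n_components, n_runs = n_runs,
                 stability_threshold = stability_threshold, fdr_q = fdr_q,
                 keep_duplicates = isTRUE(keep_duplicates),
                 optimal_alignment = isTRUE(optimal_alignment),
                 seed = as.integer(seed)),
            class = "ica_selection_config")
}

new_feature_selection <- function(indices, source_n, provenance = NULL,
                                  method = "variance") {
  stopifnot(all(indices >= 1), all(indices <= source_n))
  structure(list(indices = as.integer(indices), source_n_features = source_n,
                 provenance = provenance, method = method),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d of %d features (%s)\n",
              length(x$indices), x$source_n_features, x$method))
  invisible(x)
}

#' Select the most variable features
#'
#' Ranks rows by across-sample variance and returns the indices of the top
#' `n`, in decreasing-variance order (ties broken by original row order). The
#' standard pre-filter for methylome deconvolution: probes whose beta-values
#' vary across bulk samples are the ones carrying composition signal.
#'
#' @param d an [omic_matrix].
#' @param n number of features to keep; if `n >= n_features` all rows are
#'   returned with a warning.
#' @return a `feature_selection` with `$indices` into the rows of `d`.
#' @export
select_most_variable <- function(d, n = 5000) {
  stopifnot(inherits(d, "omic_matrix"), n >= 1)
  x <- d$values
  m <- nrow(x)
  v <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  if (n >= m) {
    if (n > m) warning("n exceeds the number of features; returning all ",
                       m, " rows", call. = FALSE)
    idx <- order(-v, seq_len(m))
  } else {
    idx <- order(-v, seq_len(m))[seq_len(n)]
  }
  new_feature_selection(idx, m, method = "variance")
}

# Align the components of S_run to those of S_ref by greedy maximum absolute
# Pearson correlation; returns the matched |r| per reference component.
align_runs_greedy <- function(S_ref, S_run) {
  cc <- abs(stats::cor(S_ref, S_run))
  k <- ncol(S_ref)
  out <- numeric(k)
  for (step in seq_len(k)) {
    pos <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out[pos[1]] <- cc[pos[1], pos[2]]
    cc[pos[1], ] <- -Inf
    cc[, pos[2]] <- -Inf
  }
  out
}

align_runs_optimal <- function(S_ref, S_run) {
  cc <- abs(stats::cor(S_ref, S_run))
  k <- ncol(S_ref)
  perms <- pracma::perms(seq_len(k))
  best <- -Inf; best_match <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    tot <- sum(cc[cbind(seq_len(k), p)])
    if (tot > best) { best <- tot; best_match <- cc[cbind(seq_len(k), p)] }
  }
  best_match
}

#' ICA-stability selection of top-contributing genes
#'
#' Runs whitened fixed-point ICA `n_runs` times with distinct seeds, aligns
#' every run's components to the first run by maximum absolute Pearson
#' correlation of the feature-loading vectors, and computes each component's
#' stability as the mean `|r|` to its aligned partners. For components with
#' stability above the threshold, run-1 loadings are standardized over
#' features, converted to two-sided normal p-values and BH-corrected within
#' the component; features with `q <= fdr_q` are selected. The union over
#' stable components is returned, deduplicated unless `keep_duplicates` —
#' keeping duplicates lets genes contributing to several components appear
#' (and hence weigh) several times in downstream factorizations.
#'
#' @param d an [omic_matrix] with more samples than `n_components`.
#' @param cfg an [ica_selection_config()].
#' @return a `feature_selection`; `$provenance` is a data.frame with one row
#'   per (feature, component) pick: `feature_id`, `component`, `loading`,
#'   `qvalue`, plus the per-component `stability` vector in
#'   `attr(, "stability")`.
#' @export
ica_stability_selection <- function(d, cfg = ica_selection_config()) {
  stopifnot(inherits(d, "omic_matrix"))
  if (ncol(d$values) <= cfg$n_components)
    stop("need n_samples > n_components for ICA", call. = FALSE)
  wh <- whiten_samples(d$values, cfg$n_components)
  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    fit <- with_seed(derive_seed(cfg$seed, "ica-run", r),
                     fastica_core(wh$z))
    if (!fit$converged) {
      warning("ICA run ", r, " did not converge; dropped", call. = FALSE)
      next
    }
    runs[[r]] <- fit$S
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (sum(ok) <= cfg$n_runs / 2)
    stop("more than half of the ICA runs failed to converge", call. = FALSE)
  runs <- runs[ok]
  S1 <- runs[[1]]
  align <- if (cfg$optimal_alignment) align_runs_optimal else align_runs_greedy
  if (length(runs) > 1) {
    match_r <- vapply(runs[-1], function(S) align(S1, S),
                      numeric(cfg$n_components))
    stability <- rowMeans(matrix(match_r, nrow = cfg$n_components))
  } else stability <- rep(1, cfg$n_components)
  stable <- which(stability > cfg$stability_threshold)
  prov <- NULL
  for (j in stable) {
    l <- S1[, j]
    z <- (l - mean(l)) / stats::sd(l)
    q <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = "BH")
    hit <- which(q <= cfg$fdr_q)
    if (length(hit))
      prov <- rbind(prov, data.frame(index = hit,
                                     feature_id = d$feature_ids[hit],
                                     component = j, loading = l[hit],
                                     qvalue = q[hit]))
  }
  if (is.null(prov)) prov <- data.frame(index = integer(),
                                        feature_id = character(),
                                        component = integer(),
                                        loading = numeric(),
                                        qvalue = numeric())
  idx <- prov$index
  if (!cfg$keep_duplicates) {
    keep <- !duplicated(idx)
    idx <- idx[keep]
    prov <- prov[keep, , drop = FALSE]
  }
  sel <- new_feature_selection(idx, nrow(d$values),
                               provenance = prov, method = "ica_stability")
  attr(sel, "stability") <- stability
  sel
}

#' Apply a feature selection to an omic matrix
#'
#' @param d an [omic_matrix].
#' @param sel a `feature_selection` produced from `d` (or a matrix of the same
#'   row count).
#' @return an [omic_matrix] restricted to the selected rows, in selection
#'   order; duplicate rows allowed when the selection carries repeats.
#' @export
apply_selection <- function(d, sel) {
  stopifnot(inherits(d, "omic_matrix"), inherits(sel, "feature_selection"))
  if (sel$source_n_features != nrow(d$values))
    stop("selection was made on a matrix with a different feature count",
         call. = FALSE)
  idx <- sel$indices
  omic_matrix(d$values[idx, , drop = FALSE], d$modality,
              feature_ids = d$feature_ids[idx], sample_ids = d$sample_ids,
              allow_duplicate_features = TRUE)
}

#' Write a feature selection as an audit TSV
#'
#' @param sel a `feature_selection`.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "feature_selection"))
  df <- sel$provenance
  if (is.null(df) || !nrow(df))
    df <- data.frame(index = sel$indices,
                     feature_id = as.character(sel$indices),
                     component = NA_integer_, loading = NA_real_,
                     qvalue = NA_real_)
  utils::write.table(df[, c("feature_id", "component", "loading", "qvalue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
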