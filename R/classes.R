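# S3 domain types: bulk feature matrices, cell-type reference profiles,
# column-stochastic proportion matrices, paired benchmark datasets and
# deconvolution results. Constructors validate; downstream code can then
# assume the invariants.

MODALITIES <- c("rna_log2", "meth_beta")

check_modality_range <- function(values, modality, what) {
  if (!all(is.finite(values)))
    stop(what, ": all entries must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (modality == "meth_beta" && (min(values) < 0 || max(values) > 1))
    stop(what, ": meth_beta entries must lie in [0, 1]", call. = FALSE)
  if (modality == "rna_log2" && min(values) < 0)
    stop(what, ": rna_log2 entries must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Construct a bulk feature-by-sample omic matrix
#'
#' The container for a bulk molecular profile matrix `D`: rows are features
#' (genes as log2-normalized expression, or CpG probes as beta-values),
#' columns are samples. Under the linear-mixture model `D = T A`, `D` is the
#' observed quantity from which cell-type proportions are estimated.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param modality `"rna_log2"` (non-negative log2 expression) or
#'   `"meth_beta"` (methylation beta-values in `[0, 1]`).
#' @param feature_ids,sample_ids row/column identifiers; default to dimnames.
#' @param allow_duplicate_features allow repeated feature ids, as produced by
#'   feature selection with duplication enabled.
#' @return an object of class `omic_matrix`.
#' @export
#' @examples
#' m <- omic_matrix(matrix(runif(6), 3, 2), "meth_beta",
#'                  feature_ids = paste0("cpg", 1:3),
#'                  sample_ids = c("s1", "s2"))
omic_matrix <- function(values, modality = c("rna_log2", "meth_beta"),
                        feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        allow_duplicate_features = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("omic_matrix needs at least one feature and one sample", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids); sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) must equal nrow(values)", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (!allow_duplicate_features && anyDuplicated(feature_ids))
    stop("feature_ids must be unique (set allow_duplicate_features for ",
         "selections that keep duplicates)", call. = FALSE)
  check_modality_range(values, modality, "omic_matrix")
  dimnames(values) <- NULL
  structure(list(values = values, modality = modality,
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 has_duplicate_features = allow_duplicate_features &&
                   anyDuplicated(feature_ids) > 0),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<omic_matrix> %d features x %d samples, modality %s\n",
              nrow(x$values), ncol(x$values), x$modality))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

#' Construct a cell-type reference-profile matrix
#'
#' The container for `T`: one column of cell-type-specific molecular profile
#' per cell type, rows matching the features of the bulk matrix it mixes into.
#'
#' @inheritParams omic_matrix
#' @param values numeric matrix, features x K cell types.
#' @param cell_type_labels K unique cell-type names.
#' @return an object of class `reference_profiles`.
#' @export
reference_profiles <- function(values, modality = c("rna_log2", "meth_beta"),
                               feature_ids = rownames(values),
                               cell_type_labels = colnames(values)) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("reference_profiles needs K >= 2", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(cell_type_labels))
    cell_type_labels <- paste0("ct", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  cell_type_labels <- as.character(cell_type_labels)
  if (length(feature_ids) != nrow(values) ||
      length(cell_type_labels) != ncol(values))
    stop("identifier lengths must match matrix dimensions", call. = FALSE)
  if (anyDuplicated(cell_type_labels))
    stop("cell_type_labels must be unique", call. = FALSE)
  check_modality_range(values, modality, "reference_profiles")
  dimnames(values) <- NULL
  structure(list(values = values, modality = modality,
                 feature_ids = feature_ids,
                 cell_type_labels = cell_type_labels),
            class = "reference_profiles")
}

#' @export
print.reference_profiles <- function(x, ...) {
  cat(sprintf("<reference_profiles> %d features x %d cell types (%s), %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$cell_type_labels, collapse = ", "), x$modality))
  invisible(x)
}

# Column-sum policy: sums within `tol_ok` of 1 pass; deviations up to
# `tol_renorm` are renormalized with a warning; anything larger is an error.
PROP_TOL_OK <- 1e-8
PROP_TOL_RENORM <- 1e-3

#' Construct a column-stochastic cell-type proportion matrix
#'
#' The container for `A`: K cell types (or anonymous estimated components) in
#' rows, samples in columns; entries in `[0, 1]`, every column summing to 1.
#' Column sums deviating from 1 by at most `1e-3` are renormalized with a
#' warning; larger deviations are rejected.
#'
#' @param values numeric K x N matrix.
#' @param row_labels K component or cell-type names.
#' @param sample_ids N sample identifiers.
#' @param labeled `TRUE` if rows are known cell types, `FALSE` for anonymous
#'   estimated components.
#' @return an object of class `proportion_matrix`.
#' @export
#' @examples
#' a <- proportion_matrix(matrix(c(.3, .7, .4, .6), 2),
#'                        row_labels = c("t1", "t2"),
#'                        sample_ids = c("s1", "s2"))
proportion_matrix <- function(values, row_labels = rownames(values),
                              sample_ids = colnames(values),
                              labeled = TRUE) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("proportion_matrix: entries must be finite", call. = FALSE)
  if (min(values) < -PROP_TOL_OK || max(values) > 1 + PROP_TOL_RENORM)
    stop("proportion_matrix: entries must lie in [0, 1]", call. = FALSE)
  values[values < 0] <- 0
  cs <- colSums(values)
  dev <- abs(cs - 1)
  if (any(dev > PROP_TOL_RENORM))
    stop(sprintf(
      "proportion_matrix: column(s) %s sum to %s; deviation from 1 exceeds %g",
      paste(which(dev > PROP_TOL_RENORM), collapse = ", "),
      paste(signif(cs[dev > PROP_TOL_RENORM], 6), collapse = ", "),
      PROP_TOL_RENORM), call. = FALSE)
  if (any(dev > PROP_TOL_OK)) {
    warning("proportion_matrix: renormalizing column sums deviating from 1 by ",
            signif(max(dev), 3), call. = FALSE)
    values <- sweep(values, 2, cs, "/")
  }
  if (is.null(row_labels)) row_labels <- paste0("k", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  row_labels <- as.character(row_labels); sample_ids <- as.character(sample_ids)
  if (length(row_labels) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths must match matrix dimensions", call. = FALSE)
  dimnames(values) <- NULL
  structure(list(values = values, row_labels = row_labels,
                 sample_ids = sample_ids, labeled = isTRUE(labeled)),
            class = "proportion_matrix")
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("<proportion_matrix> %d %s x %d samples\n", nrow(x$values),
              if (x$labeled) "cell types" else "anonymous components",
              ncol(x$values)))
  invisible(x)
}

#' Bundle one paired multi-omic benchmark dataset
#'
#' One realization of the simulation: paired bulk methylome and transcriptome
#' built from the *same* proportion matrix, plus (optionally hidden) ground
#' truth `A`, `T_MET`, `T_RNA` and provenance metadata.
#'
#' @param d_met,d_rna [omic_matrix] bulk matrices sharing sample ids/order.
#' @param a_true optional true [proportion_matrix] (labeled).
#' @param t_met,t_rna optional [reference_profiles] used for mixing.
#' @param meta named list of simulation provenance (seed, dataset index,
#'   Dirichlet and noise parameters).
#' @return an object of class `benchmark_dataset`; `has_truth(ds)` reports
#'   whether `a_true` is present.
#' @export
benchmark_dataset <- function(d_met, d_rna, a_true = NULL, t_met = NULL,
                              t_rna = NULL, meta = list()) {
  stopifnot(inherits(d_met, "omic_matrix"), inherits(d_rna, "omic_matrix"))
  if (!identical(d_met$sample_ids, d_rna$sample_ids))
    stop("d_met and d_rna must share sample ids in the same order",
         call. = FALSE)
  if (!is.null(a_true)) {
    stopifnot(inherits(a_true, "proportion_matrix"))
    if (!identical(a_true$sample_ids, d_met$sample_ids))
      stop("a_true sample ids must match the bulk matrices", call. = FALSE)
  }
  for (t in list(t_met, t_rna)) if (!is.null(t))
    stopifnot(inherits(t, "reference_profiles"))
  if (!is.null(a_true)) {
    for (t in list(t_met, t_rna)) if (!is.null(t) &&
        !identical(t$cell_type_labels, a_true$row_labels))
      stop("reference profile cell types must match a_true row labels",
           call. = FALSE)
  }
  structure(list(d_met = d_met, d_rna = d_rna, a_true = a_true,
                 t_met = t_met, t_rna = t_rna, meta = meta),
            class = "benchmark_dataset")
}

#' @rdname benchmark_dataset
#' @param ds a `benchmark_dataset`.
#' @export
has_truth <- function(ds) !is.null(ds$a_true)

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_dataset> %d samples; %d CpGs, %d genes; ",
                     "truth %s\n"),
              length(x$d_met$sample_ids), nrow(x$d_met$values),
              nrow(x$d_rna$values), if (has_truth(x)) "present" else "hidden"))
  invisible(x)
}

#' Construct a deconvolution result
#'
#' Wraps an estimated proportion matrix together with optional estimated
#' reference profiles and a diagnostics log (objective trace, iteration
#' counts, initialization used).
#'
#' @param a_est estimated [proportion_matrix] (anonymous components unless the
#'   method is reference-based).
#' @param method_id identifier of the producing method.
#' @param run_seed seed the run was executed under.
#' @param t_est_rna,t_est_met optional estimated [reference_profiles].
#' @param elapsed_seconds wall-clock time of the run.
#' @param diagnostics named list of per-stage logs.
#' @return an object of class `deconvolution_result`.
#' @export
deconvolution_result <- function(a_est, method_id, run_seed = NA_integer_,
                                 t_est_rna = NULL, t_est_met = NULL,
                                 elapsed_seconds = NA_real_,
                                 diagnostics = list()) {
  stopifnot(inherits(a_est, "proportion_matrix"))
  structure(list(a_est = a_est, method_id = method_id, run_seed = run_seed,
                 t_est_rna = t_est_rna, t_est_met = t_est_met,
                 elapsed_seconds = elapsed_seconds, diagnostics = diagnostics),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> method %s: %d components x %d samples\n",
              x$method_id, nrow(x$a_est$values), ncol(x$a_est$values)))
  invisible(x)
}
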