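# Reference-based deconvolution: per-sample regression of the bulk profile
# on known cell-type reference profiles (ordinary or Huber-robust least
# squares), then non-negative renormalization to proportions.

#' Reference-based deconvolution by per-sample regression
#'
#' For each sample, regresses the bulk column on the reference-profile
#' columns over their common features (inner join on feature ids): `"ols"`
#' uses the closed-form least-squares solution, `"rlr"` iteratively
#' reweighted least squares with Huber weights (tuning constant 1.345, the
#' 95%-Gaussian-efficiency convention, via [MASS::rlm()]). Negative
#' coefficients are clamped to 0 and each sample is normalized to sum to 1;
#' an all-zero coefficient vector falls back to uniform with a warning.
#' Because the reference cell types are known, the output is labeled — no
#' component matching is needed for scoring.
#'
#' @param d an [omic_matrix].
#' @param t_ref a [reference_profiles] with at least K features in common
#'   with `d`.
#' @param method `"ols"` or `"rlr"`.
#' @return a labeled [deconvolution_result].
#' @export
reference_regression <- function(d, t_ref, method = c("ols", "rlr")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "omic_matrix"), inherits(t_ref, "reference_profiles"))
  common <- intersect(d$feature_ids, t_ref$feature_ids)
  K <- ncol(t_ref$values)
  if (length(common) < K)
    stop("fewer common features (", length(common), ") than cell types (",
         K, ")", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  X <- t_ref$values[match(common, t_ref$feature_ids), , drop = FALSE]
  Y <- d$values[match(common, d$feature_ids), , drop = FALSE]
  n <- ncol(Y)
  coefs <- matrix(0, K, n)
  if (method == "ols") {
    coefs <- qr.solve(X, Y)
  } else {
    for (j in seq_len(n))
      coefs[, j] <- stats::coef(MASS::rlm(X, Y[, j], psi = MASS::psi.huber,
                                          k = 1.345, maxit = 100))
  }
  coefs[coefs < 0] <- 0
  cs <- colSums(coefs)
  if (any(cs == 0)) {
    warning("zero coefficient vector in sample(s) ",
            paste(d$sample_ids[cs == 0], collapse = ", "),
            "; using uniform fallback", call. = FALSE)
    coefs[, cs == 0] <- 1 / K
    cs <- colSums(coefs)
  }
  a <- sweep(coefs, 2, cs, "/")
  deconvolution_result(
    proportion_matrix(a, row_labels = t_ref$cell_type_labels,
                      sample_ids = d$sample_ids, labeled = TRUE),
    method_id = paste0("ref_", toupper(method)),
    elapsed_seconds = proc.time()[["elapsed"]] - t0,
    diagnostics = list(n_common_features = length(common), method = method))
}
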