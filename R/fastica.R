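# Whitened fixed-point ICA (logcosh contrast, symmetric decorrelation).
# The data matrix is features x samples; feature rows are treated as
# observations of the sample-space variables, so the estimated sources are
# feature-loading vectors — the orientation used throughout gene-expression
# ICA, where components describe independent patterns over genes/probes.

sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% w
}

# Whitening of the sample space: returns the centered data projected onto k
# unit-variance principal directions (features x k) — deterministic, so it
# can be shared across repeated ICA runs on the same matrix.
whiten_samples <- function(x, k) {
  p <- ncol(x)
  if (k > p) stop("n_components must not exceed the number of samples",
                  call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / nrow(xc)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[k] < 1e-12 * e$values[1])
    stop("data rank below n_components; cannot whiten", call. = FALSE)
  list(z = xc %*% (e$vectors[, seq_len(k), drop = FALSE] %*%
                     diag(1 / sqrt(e$values[seq_len(k)]), k)),
       xc = xc)
}

# One fixed-point ICA estimation on pre-whitened data z (n x k): random
# unmixing start from the caller's RNG, symmetric fixed-point updates in
# compiled code. Components without non-Gaussian signal (whitened noise
# directions) cycle among near-fixed points indefinitely, so the kernel
# keeps the iterate closest to a fixed point (criterion: max over
# components of 1 - |cos| between successive unmixing directions, early
# stop below tol). Signal-bearing components settle to ~1e-5; noise
# components hover around 1e-3..5e-2 depending on the data. A run is
# declared non-converged only when it genuinely diverges (best criterion
# above fail_tol, or non-finite output) — the multi-run stability analysis,
# not this flag, judges component quality.
fastica_core <- function(z, max_iter = 200, tol = 1e-2, fail_tol = 0.2) {
  k <- ncol(z)
  w0 <- matrix(stats::rnorm(k * k), k)
  fit <- .fastica_sym_cpp(z, w0, max_iter, tol)
  ok <- all(is.finite(fit$W)) && is.finite(fit$delta) && fit$delta < fail_tol
  list(S = z %*% t(fit$W), W = fit$W, converged = ok,
       n_iter = fit$n_iter, delta = fit$delta)
}

skewness <- function(x) {
  xc <- x - mean(x)
  mean(xc^3) / (stats::sd(x)^3 + .Machine$double.eps)
}

# Orient each component so its loading distribution is positively skewed:
# marker-driven components then have their defining features at the top.
orient_by_skewness <- function(S) {
  flip <- apply(S, 2, skewness) < 0
  S[, flip] <- -S[, flip]
  S
}
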