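# Constrained quadratic programming primitives for deconvolution:
#   qp_simplex — min 0.5 x'Qx + c'x  s.t.  sum(x) = 1, x >= 0
#   qp_box     — min 0.5 x'Qx + c'x  s.t.  lower <= x <= upper
# Both are primal active-set solvers for small positive-definite systems
# (K is the number of cell types, typically 5), deterministic, exact up to
# linear-algebra round-off. cd_box_rows solves many box problems sharing one
# Hessian at once by vectorized cyclic coordinate descent — the workhorse of
# the NMF T-updates, where every feature row shares the Hessian A A'.

QP_EPS <- 1e-11

solve_ridge <- function(M, rhs) {
  tryCatch(solve(M, rhs), error = function(e) {
    solve(M + diag(1e-10 * (1 + mean(abs(diag(M)))), nrow(M)), rhs)
  })
}

qp_simplex <- function(Q, cvec, max_pass = NULL) {
  K <- length(cvec)
  if (is.null(max_pass)) max_pass <- 4L * K * K + 20L
  x <- rep(1 / K, K)
  fixed <- rep(FALSE, K)
  for (pass in seq_len(max_pass)) {
    free <- which(!fixed)
    nf <- length(free)
    M <- rbind(cbind(Q[free, free, drop = FALSE], rep(1, nf)),
               c(rep(1, nf), 0))
    sol <- solve_ridge(M, c(-cvec[free], 1))
    xf <- sol[seq_len(nf)]
    mu <- sol[nf + 1]
    if (all(xf >= -QP_EPS)) {
      x[] <- 0
      x[free] <- pmax(xf, 0)
      lambda <- as.numeric(Q %*% x + cvec + mu)
      viol <- fixed & (lambda < -1e-9)
      if (!any(viol)) return(x)
      fixed[which(viol)[which.min(lambda[viol])]] <- FALSE
    } else {
      x_new <- numeric(K)
      x_new[free] <- xf
      d <- x_new - x
      shrink <- free[d[free] < -QP_EPS]
      alpha <- (0 - x[shrink]) / d[shrink]
      j <- shrink[which.min(alpha)]
      x <- x + min(alpha) * d
      x[j] <- 0
      x[fixed] <- 0
      fixed[j] <- TRUE
    }
  }
  x / sum(x)
}

qp_box <- function(Q, cvec, lower, upper, max_pass = NULL) {
  K <- length(cvec)
  lower <- rep_len(lower, K); upper <- rep_len(upper, K)
  if (is.null(max_pass)) max_pass <- 6L * K * K + 30L
  # feasible start: clipped unconstrained solution
  x <- pmin(pmax(as.numeric(solve_ridge(Q, -cvec)), lower), upper)
  state <- integer(K)                       # -1 lower, 0 free, +1 upper
  state[x <= lower + QP_EPS] <- -1L
  state[x >= upper - QP_EPS] <- 1L
  x[state == -1L] <- lower[state == -1L]
  x[state == 1L] <- upper[state == 1L]
  for (pass in seq_len(max_pass)) {
    free <- which(state == 0L)
    if (length(free)) {
      bound <- which(state != 0L)
      rhs <- -cvec[free]
      if (length(bound))
        rhs <- rhs - Q[free, bound, drop = FALSE] %*% x[bound]
      xf <- as.numeric(solve_ridge(Q[free, free, drop = FALSE], rhs))
      inside <- xf >= lower[free] - QP_EPS & xf <= upper[free] + QP_EPS
      if (!all(inside)) {
        x_new <- x; x_new[free] <- xf
        d <- x_new - x
        alpha <- 1; j <- 0L; jdir <- 0L
        for (i in free) {
          if (d[i] < -QP_EPS) {
            a <- (lower[i] - x[i]) / d[i]
            if (a < alpha) { alpha <- a; j <- i; jdir <- -1L }
          } else if (d[i] > QP_EPS) {
            a <- (upper[i] - x[i]) / d[i]
            if (a < alpha) { alpha <- a; j <- i; jdir <- 1L }
          }
        }
        x <- x + alpha * d
        if (j > 0L) {
          state[j] <- jdir
          x[j] <- if (jdir < 0L) lower[j] else upper[j]
        }
        next
      }
      x[free] <- pmin(pmax(xf, lower[free]), upper[free])
    }
    g <- as.numeric(Q %*% x + cvec)
    viol_low <- state == -1L & g < -1e-9
    viol_up <- state == 1L & g > 1e-9
    if (!any(viol_low | viol_up)) return(x)
    cand <- which(viol_low | viol_up)
    state[cand[which.max(abs(g[cand]))]] <- 0L
  }
  x
}

#' Simplex-constrained least squares
#'
#' Solves `argmin || d_col - t %*% a ||^2` subject to `a >= 0` and
#' `sum(a) = 1` — the per-sample proportion estimate under the linear mixture
#' model with the biological constraint that cell fractions are non-negative
#' and exhaustive. Solved exactly by a primal active-set quadratic program;
#' deterministic.
#'
#' @param t numeric m x K matrix of reference profiles (full column rank
#'   preferred, not required).
#' @param d_col numeric m-vector, one bulk sample.
#' @return a K-vector on the probability simplex.
#' @export
#' @examples
#' simplex_lsq(diag(2), c(0.3, 0.7))  # already on the simplex
simplex_lsq <- function(t, d_col) {
  t <- as.matrix(t)
  stopifnot(nrow(t) == length(d_col))
  qp_simplex(crossprod(t), -as.numeric(crossprod(t, d_col)))
}

#' Box-constrained least squares for one reference-profile row
#'
#' Solves `argmin || d_row - t %*% a ||^2` over `t` in
#' `[lower, upper]^K`, where `a` is the (K x n) proportion matrix and `d_row`
#' the bulk values of one feature across samples — the per-feature
#' reference-profile update under e.g. the `0 <= T <= 1` beta-value
#' constraint. Exact primal active-set solution; deterministic.
#'
#' @param a numeric K x n proportion matrix.
#' @param d_row numeric n-vector.
#' @param lower,upper box bounds (scalars or K-vectors); `upper = Inf` gives
#'   non-negative least squares.
#' @return a K-vector within the box.
#' @export
box_lsq <- function(a, d_row, lower = 0, upper = 1) {
  a <- as.matrix(a)
  stopifnot(ncol(a) == length(d_row), all(lower < upper))
  qp_box(tcrossprod(a), -as.numeric(a %*% d_row), lower, upper)
}

# Vectorized cyclic coordinate descent for m box-constrained quadratics
# sharing the Hessian Q: minimize per row i of Tm,
#   0.5 t' Q t + Cmat[i, ] t ,  lower <= t <= upper.
# Monotone per coordinate update; iterated to max-change tolerance.
cd_box_rows <- function(Tm, Q, Cmat, lower = 0, upper = 1,
                        max_sweep = 200L, tol = 1e-10) {
  .cd_box_rows_cpp(Tm, Q, Cmat, lower, upper, as.integer(max_sweep), tol)
}
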