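// Numerical kernels for the deconvolution loops: symmetric fixed-point ICA,
// vectorized box-constrained coordinate descent with a shared Hessian, and
// batched simplex-constrained quadratic programs (one per sample column).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sym_decorrelate_cpp(const mat& w) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, w * w.t());
  eval = clamp(eval, datum::eps, datum::inf);
  return evec * diagmat(1.0 / sqrt(eval)) * evec.t() * w;
}

// Symmetric fixed-point ICA (logcosh contrast) on pre-whitened z (n x k),
// starting from w0. Tracks the iterate with the smallest convergence
// criterion and returns it: on data whose trailing components are pure
// noise the iteration can cycle, and the best visited near-fixed point is
// the meaningful answer. Converged when the best criterion dips below tol.
// [[Rcpp::export(name = ".fastica_sym_cpp")]]
Rcpp::List fastica_sym_cpp(const arma::mat& z, const arma::mat& w0,
                           int max_iter, double tol) {
  const double n = static_cast<double>(z.n_rows);
  const int stall_limit = 60;  // stop once the best iterate stops improving
  mat w = sym_decorrelate_cpp(w0);
  mat best_w = w;
  double best_delta = datum::inf;
  int it = 0, best_it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    mat wz = z * w.t();
    mat g = tanh(wz);
    rowvec gprime_mean = mean(1.0 - square(g), 0);
    mat w_new = g.t() * z / n - diagmat(gprime_mean.t()) * w;
    w_new = sym_decorrelate_cpp(w_new);
    double delta = max(abs(abs(sum(w_new % w, 1)) - 1.0));
    w = w_new;
    if (delta < best_delta) {
      best_delta = delta;
      best_w = w;
      best_it = it;
    }
    if (best_delta < tol) {
      converged = true;
      break;
    }
    if (it - best_it >= stall_limit) break;
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = best_w, Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iter") = std::min(it, max_iter),
      Rcpp::Named("delta") = best_delta);
}

// Cyclic coordinate descent for m box-constrained quadratics sharing one
// Hessian Q (K x K): minimize per row i of Tm, 0.5 t' Q t + C[i, ] t over
// [lower, upper]^K. Monotone per update; iterated to max-change tol.
// [[Rcpp::export(name = ".cd_box_rows_cpp")]]
arma::mat cd_box_rows_cpp(arma::mat Tm, const arma::mat& Q,
                          const arma::mat& C, double lower, double upper,
                          int max_sweep, double tol) {
  const uword K = Tm.n_cols;
  const uword m = Tm.n_rows;
  mat G = Tm * Q + C;
  const vec dQ = Q.diag();
  vec dj(m);
  for (int sweep = 0; sweep < max_sweep; ++sweep) {
    double biggest = 0.0;
    for (uword j = 0; j < K; ++j) {
      double* tcol = Tm.colptr(j);
      const double* gcol = G.colptr(j);
      const double inv = 1.0 / dQ(j);
      double* d = dj.memptr();
      double mx = 0.0;
      for (uword i = 0; i < m; ++i) {
        double tnew = tcol[i] - gcol[i] * inv;
        if (tnew < lower) tnew = lower;
        else if (tnew > upper) tnew = upper;
        d[i] = tnew - tcol[i];
        tcol[i] = tnew;
        double a = std::abs(d[i]);
        if (a > mx) mx = a;
      }
      if (mx > 0.0) {
        for (uword l = 0; l < K; ++l) {
          const double q = Q(j, l);
          if (q != 0.0) {
            double* gl = G.colptr(l);
            for (uword i = 0; i < m; ++i) gl[i] += d[i] * q;
          }
        }
        if (mx > biggest) biggest = mx;
      }
    }
    if (biggest < tol) break;
  }
  return Tm;
}

// Primal active-set solver: min 0.5 a'Qa + c'a  s.t.  sum(a) = 1, a >= 0.
static vec qp_simplex_cpp(const mat& Q, const vec& cvec) {
  const uword K = cvec.n_elem;
  const double eps = 1e-11;
  vec x(K, fill::value(1.0 / K));
  uvec fixed(K, fill::zeros);
  const int max_pass = 4 * static_cast<int>(K) * static_cast<int>(K) + 20;
  for (int pass = 0; pass < max_pass; ++pass) {
    uvec free = find(fixed == 0);
    const uword nf = free.n_elem;
    mat M(nf + 1, nf + 1, fill::ones);
    M(nf, nf) = 0.0;
    M.submat(0, 0, nf - 1, nf - 1) = Q.submat(free, free);
    vec rhs(nf + 1);
    rhs.head(nf) = -cvec.elem(free);
    rhs(nf) = 1.0;
    vec sol;
    if (!solve(sol, M, rhs)) {
      M.submat(0, 0, nf - 1, nf - 1).diag() += 1e-10;
      sol = solve(M, rhs);
    }
    vec xf = sol.head(nf);
    double mu = sol(nf);
    if (xf.min() >= -eps) {
      x.zeros();
      x.elem(free) = clamp(xf, 0.0, datum::inf);
      vec lambda = Q * x + cvec + mu;
      uvec viol = find((fixed == 1) % (lambda < -1e-9));
      if (viol.n_elem == 0) return x;
      uword worst = viol(lambda.elem(viol).index_min());
      fixed(worst) = 0;
    } else {
      vec x_new(K, fill::zeros);
      x_new.elem(free) = xf;
      vec d = x_new - x;
      double alpha = datum::inf;
      uword j = K;
      for (uword i = 0; i < nf; ++i) {
        uword idx = free(i);
        if (d(idx) < -eps) {
          double a = -x(idx) / d(idx);
          if (a < alpha) {
            alpha = a;
            j = idx;
          }
        }
      }
      x += alpha * d;
      x(j) = 0.0;
      x.elem(find(fixed == 1)).zeros();
      fixed(j) = 1;
    }
  }
  return x / accu(x);
}

// Solve one simplex QP per column of D: A[, j] = argmin ||d_j - T a||^2 on
// the probability simplex, sharing Q = T'T across columns.
// [[Rcpp::export(name = ".simplex_cols_cpp")]]
arma::mat simplex_cols_cpp(const arma::mat& Q, const arma::mat& TtD) {
  mat A(Q.n_rows, TtD.n_cols);
  for (uword j = 0; j < TtD.n_cols; ++j)
    A.col(j) = qp_simplex_cpp(Q, -TtD.col(j));
  return A;
}
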