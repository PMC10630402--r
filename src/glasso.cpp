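#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso by blockwise coordinate descent (Friedman, Hastie &
// Tibshirani 2008): maximizes log det(Theta) - tr(S Theta) - rho ||Theta||_1
// (off-diagonal L1 penalty; the diagonal is additionally penalized when
// penalize_diagonal is true). W estimates the covariance Theta^{-1}.
// W_init / B_init allow warm starts along a penalty path.
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double rho,
                     const arma::mat& W_init, const arma::mat& B_init,
                     bool penalize_diagonal, int maxit, double tol) {
  const int p = S.n_rows;
  mat W = W_init;
  mat B = B_init;                 // column j holds beta for block j (diag 0)
  W.diag() = S.diag() + (penalize_diagonal ? rho : 0.0);

  // convergence threshold scaled by mean absolute off-diagonal of S
  double soff = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) soff += std::fabs(S(i, j));
  double thr = tol * (p > 1 ? soff / (p * (p - 1)) : 1.0);
  if (thr <= 0) thr = tol;

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = (p == 1);
  for (int it = 0; it < maxit && !converged; ++it) {
    double dW = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      beta = beta(idx);
      // lasso coordinate descent on beta
      for (int inner = 0; inner < maxit; ++inner) {
        double dmax = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double grad = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
          double nb = soft(grad, rho) / W11(k, k);
          if (nb != old) {
            beta(k) = nb;
            double d = std::fabs(nb - old);
            if (d > dmax) dmax = d;
          }
        }
        if (dmax < thr * 0.1) break;
      }
      vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > dW) dW = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (dW <= thr) converged = true;
  }

  // recover the precision matrix from the final W and betas
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec beta = B.col(j);
    beta = beta(idx);
    vec w12 = W.col(j);
    w12 = w12(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k)
      Theta(idx(k), j) = -beta(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  // exact zeros where beta was zero on both sides
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j && B(i, j) == 0.0 && B(j, i) == 0.0) Theta(i, j) = 0.0;

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta,
                            Rcpp::Named("beta") = B,
                            Rcpp::Named("converged") = converged);
}
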