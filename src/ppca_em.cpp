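// EM for probabilistic PCA with missing data.
// Maximises the observed-data likelihood: missing entries are marginalised
// out, so each row i contributes N(x_{o_i}; mu_{o_i}, W_{o_i} W_{o_i}' +
// sigma2 I). This gives the monotone log-likelihood EM guarantees.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List ppca_em_cpp(const arma::mat& X, const arma::mat& W0,
                       const arma::vec& mu0, double s20,
                       int maxIter, double tol) {
  const uword n = X.n_rows, d = X.n_cols, k = W0.n_cols;
  mat W = W0;
  vec mu = mu0;
  double s2 = s20;
  std::vector<uvec> obs(n);
  uword Nobs = 0;
  for (uword i = 0; i < n; ++i) {
    obs[i] = find_finite(X.row(i).t());
    Nobs += obs[i].n_elem;
  }
  std::vector<double> llTrace;
  bool converged = false;
  mat Z(n, k, fill::zeros);
  cube V(k, k, n, fill::zeros);
  const double log2pi = std::log(2.0 * M_PI);

  for (int iter = 0; iter < maxIter; ++iter) {
    // E-step (and observed-data log-likelihood of the current parameters)
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      const uvec& o = obs[i];
      const uword dO = o.n_elem;
      mat Wo = W.rows(o);
      vec xo = X.row(i).t();
      xo = xo.elem(o) - mu.elem(o);
      mat M = Wo.t() * Wo;
      M.diag() += s2;
      mat Minv = inv_sympd(M);
      vec Wtx = Wo.t() * xo;
      vec z = Minv * Wtx;
      Z.row(i) = z.t();
      V.slice(i) = s2 * Minv;
      double ldM, sgn;
      log_det(ldM, sgn, M);
      // |C_o| = s2^(dO - k) |M|  (matrix determinant lemma)
      double logdetC = (double(dO) - double(k)) * std::log(s2) + ldM;
      double quad = (dot(xo, xo) - dot(Wtx, z)) / s2;  // Woodbury
      ll += -0.5 * (double(dO) * log2pi + logdetC + quad);
    }
    llTrace.push_back(ll);
    if (llTrace.size() > 1) {
      double prev = llTrace[llTrace.size() - 2];
      if (std::fabs(ll - prev) / (std::fabs(prev) + 1e-12) < tol) {
        converged = true;
        break;
      }
    }

    // M-step: joint (mu_j, W_j) per feature from the rows observing j
    cube A(k + 1, k + 1, d, fill::zeros);
    mat B(k + 1, d, fill::zeros);
    vec zt(k + 1);
    mat Ai(k + 1, k + 1);
    for (uword i = 0; i < n; ++i) {
      const uvec& o = obs[i];
      vec z = Z.row(i).t();
      mat S = V.slice(i) + z * z.t();
      Ai(0, 0) = 1.0;
      Ai.submat(0, 1, 0, k) = z.t();
      Ai.submat(1, 0, k, 0) = z;
      Ai.submat(1, 1, k, k) = S;
      zt(0) = 1.0;
      zt.subvec(1, k) = z;
      for (uword jj = 0; jj < o.n_elem; ++jj) {
        const uword j = o(jj);
        A.slice(j) += Ai;
        B.col(j) += X(i, j) * zt;
      }
    }
    for (uword j = 0; j < d; ++j) {
      vec sol = solve(A.slice(j), B.col(j));
      mu(j) = sol(0);
      W.row(j) = sol.subvec(1, k).t();
    }

    // sigma2 with updated (mu, W); E-step moments fixed (exact M-step:
    // the (mu, W) optimum does not depend on sigma2)
    double acc = 0.0;
    for (uword i = 0; i < n; ++i) {
      const uvec& o = obs[i];
      mat Wo = W.rows(o);
      vec z = Z.row(i).t();
      vec xo = X.row(i).t();
      xo = xo.elem(o);
      vec r = xo - mu.elem(o) - Wo * z;
      acc += dot(r, r) + accu((Wo * V.slice(i)) % Wo);
    }
    s2 = std::max(acc / double(Nobs), 1e-12);
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma2") = s2,
    Rcpp::Named("loglik") = llTrace,
    Rcpp::Named("converged") = converged);
}
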