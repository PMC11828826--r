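#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// ADMM iteration for variational mode decomposition, run entirely on the
// non-negative half-spectrum of the (mirror-extended) input signal.
//
// Per sweep, for each mode k:
//   u_k <- (f - sum_{i != k} u_i + lambda/2) / (1 + 2 alpha (om - omega_k)^2)
//   omega_k <- sum(om |u_k|^2) / sum(|u_k|^2)
// then lambda <- lambda + tau (f - sum_k u_k).
// Terminates when the summed relative spectral change drops below tol.
//
// fhp:    input half-spectrum (complex, length M)
// om:     normalized frequency grid in cycles/sample, 0 .. ~0.5 (length M)
// omega0: initial center frequencies (length K)
// [[Rcpp::export]]
Rcpp::List vmd_admm_cpp(const arma::cx_vec& fhp, const arma::vec& om,
                        const arma::vec& omega0, double alpha, double tau,
                        double tol, int max_iter) {
  typedef std::complex<double> cx;
  const size_t M = fhp.n_elem;
  const size_t K = omega0.n_elem;

  arma::cx_mat u(M, K, arma::fill::zeros);
  arma::cx_mat u_prev(M, K, arma::fill::zeros);
  arma::cx_vec lambda(M, arma::fill::zeros);
  arma::cx_vec sum_u(M, arma::fill::zeros);
  arma::vec omega = omega0;

  int n = 0;
  double res = std::numeric_limits<double>::infinity();
  const double floor_ = 1e-14;

  while (n < max_iter && res > tol) {
    u_prev = u;
    for (size_t k = 0; k < K; ++k) {
      cx* uk = u.colptr(k);
      const double wk = omega[k];
      double acc_p = 0.0, acc_op = 0.0;
      for (size_t m = 0; m < M; ++m) {
        sum_u[m] -= uk[m];
        const double d = om[m] - wk;
        const cx val = (fhp[m] - sum_u[m] + 0.5 * lambda[m]) /
                       (1.0 + 2.0 * alpha * d * d);
        uk[m] = val;
        const double p = std::norm(val);
        acc_p += p;
        acc_op += om[m] * p;
        sum_u[m] += val;
      }
      if (acc_p > 1e-300) omega[k] = acc_op / acc_p;
    }
    if (tau != 0.0)
      for (size_t m = 0; m < M; ++m) lambda[m] += tau * (fhp[m] - sum_u[m]);
    res = 0.0;
    for (size_t k = 0; k < K; ++k) {
      const cx* uk = u.colptr(k);
      const cx* up = u_prev.colptr(k);
      double num = 0.0, den = 0.0;
      for (size_t m = 0; m < M; ++m) {
        num += std::norm(uk[m] - up[m]);
        den += std::norm(up[m]);
      }
      res += num / std::max(den, floor_);
    }
    ++n;
  }

  return Rcpp::List::create(
    Rcpp::Named("u_hat") = u,
    Rcpp::Named("omega") = omega,
    Rcpp::Named("n_iter") = n,
    Rcpp::Named("residual") = res);
}
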