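#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Covariance of one additive component.
// Every component is written as  K_c = v * M % exp(-Q / ell^2)  where
//   Q is a fixed nonnegative "distance" matrix (NULL for categorical kernels;
//     squared-exponential kernels fold the 1/2 into Q, periodic kernels store
//     2 sin^2(pi * dt / period)),
//   M is a fixed 0/1 mask (NULL means all ones; categorical and product
//     kernels use the same-level indicator).
static arma::mat comp_cov(const double v, const double ell, SEXP Qs, SEXP Ms,
                          const int n) {
  const bool hasQ = Qs != R_NilValue;
  const bool hasM = Ms != R_NilValue;
  // alias the R memory; these matrices are read-only here
  const arma::mat Q = hasQ ?
    arma::mat(REAL(Qs), n, n, false, true) : arma::mat();
  const arma::mat M = hasM ?
    arma::mat(REAL(Ms), n, n, false, true) : arma::mat();
  const double inv_l2 = 1.0 / (ell * ell);
  arma::mat K(n, n);
  // symmetric; the exp is evaluated only on the lower triangle and only
  // where the categorical mask is nonzero
  for (int j = 0; j < n; ++j) {
    for (int i = j; i < n; ++i) {
      double val = v;
      if (hasM) val *= M(i, j);
      if (val != 0.0 && hasQ) val *= std::exp(-Q(i, j) * inv_l2);
      K(i, j) = val;
      K(j, i) = val;
    }
  }
  return K;
}

// Negative log marginal likelihood of an additive GP and its gradient with
// respect to the log-scale hyperparameters.
//
// par layout: for each component c in order: log v_c, then log ell_c if
// has_ls[c]; the final entry is log sigma2 (noise variance).
//
// The Cholesky factorisation is attempted with no jitter first, then with an
// escalating diagonal jitter (jitter0, 10*jitter0, ... up to jitter_max).
// [[Rcpp::export]]
List agp_nll_grad(const arma::vec& par, const List& Q, const List& M,
                  const LogicalVector& has_ls, const arma::vec& y,
                  const double jitter0 = 1e-8, const double jitter_max = 1e-4) {
  const int n = y.n_elem;
  const int nc = Q.size();
  const int npar = par.n_elem;

  std::vector<arma::mat> Kc(nc);
  std::vector<double> ells(nc, 1.0);
  arma::mat K(n, n, arma::fill::zeros);
  int idx = 0;
  for (int c = 0; c < nc; ++c) {
    const double v = std::exp(par(idx++));
    double ell = 1.0;
    if (has_ls[c]) ell = std::exp(par(idx++));
    ells[c] = ell;
    Kc[c] = comp_cov(v, ell, Q[c], M[c], n);
    K += Kc[c];
  }
  const double noise = std::exp(par(idx));
  K.diag() += noise;

  arma::mat R;
  double jit = 0.0;
  bool ok = arma::chol(R, K);
  if (!ok) {
    jit = jitter0;
    while (jit <= jitter_max * 1.0000001) {
      arma::mat Kj = K;
      Kj.diag() += jit;
      ok = arma::chol(R, Kj);
      if (ok) break;
      jit *= 10.0;
    }
  }
  if (!ok) {
    return List::create(_["nll"] = 1e10,
                        _["grad"] = NumericVector(npar),
                        _["ok"] = false,
                        _["jitter"] = NA_REAL);
  }

  const arma::mat Rinv = arma::inv(arma::trimatu(R));
  const arma::mat Kinv = Rinv * Rinv.t();
  const arma::vec alpha = Kinv * y;
  const double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  const double nll = 0.5 * arma::dot(y, alpha) + 0.5 * logdet +
                     0.5 * n * std::log(2.0 * M_PI);

  // d nll / d theta = 0.5 * tr((Kinv - alpha alpha') dK/dtheta)
  const arma::mat A = Kinv - alpha * alpha.t();
  arma::vec grad(npar, arma::fill::zeros);
  idx = 0;
  for (int c = 0; c < nc; ++c) {
    grad(idx++) = 0.5 * arma::accu(A % Kc[c]);  // wrt log v_c
    if (has_ls[c]) {
      const arma::mat Qc = as<arma::mat>(Q[c]);
      // K_c = v M exp(-Q/ell^2): dK/dlog ell = K_c % Q * 2 / ell^2
      grad(idx++) = arma::accu(A % (Kc[c] % Qc)) / (ells[c] * ells[c]);
    }
  }
  grad(idx) = 0.5 * arma::trace(A) * noise;  // wrt log sigma2

  return List::create(_["nll"] = nll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()),
                      _["ok"] = true,
                      _["jitter"] = jit);
}
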