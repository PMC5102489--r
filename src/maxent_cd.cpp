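#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Penalized maximum-entropy fit over background cells.
//
// Maximizes, in lambda, the per-presence log-likelihood of the Gibbs
// distribution raw(x) = exp(eta_x) / Z over the background,
//
//   J(lambda) = sum_j pbar_j lambda_j - log Z(lambda) - sum_j beta_j |lambda_j|
//
// by proximal Newton: at each outer iteration the smooth part is expanded
// to second order around the current lambda (gradient pbar - E_raw[f],
// Hessian -Cov_raw[f]) and the L1-penalized quadratic subproblem is solved
// by coordinate descent with soft-thresholding; a backtracking line search
// on the true objective guarantees ascent.  At convergence the KKT
// conditions give |E_raw[f_j] - pbar_j| <= beta_j for every feature.

static double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double obj_value(const arma::vec& eta, const arma::vec& pbar,
                        const arma::vec& beta, const arma::vec& lambda) {
  double m = eta.max();
  double lz = std::log(arma::accu(arma::exp(eta - m))) + m;
  return arma::dot(pbar, lambda) - lz - arma::dot(beta, arma::abs(lambda));
}

// [[Rcpp::export]]
List maxent_fit_cpp(const arma::mat& F, const arma::vec& pbar,
                    const arma::vec& beta, double tol, int max_iter) {
  const arma::uword n = F.n_rows, J = F.n_cols;
  arma::vec lambda(J, arma::fill::zeros), eta(n, arma::fill::zeros);
  double max_update = arma::datum::inf;
  int iter = 0;
  double obj = obj_value(eta, pbar, beta, lambda);

  for (iter = 0; iter < max_iter; ++iter) {
    // raw weights and moments of the features under raw
    arma::vec w = arma::exp(eta - eta.max());
    w /= arma::accu(w);
    arma::vec e = F.t() * w;
    arma::mat Fw = F.each_col() % arma::sqrt(w);
    arma::mat H = Fw.t() * Fw - e * e.t();   // Cov_raw[f]

    // inner coordinate descent on the L1-penalized quadratic model
    arma::vec delta(J, arma::fill::zeros), Hd(J, arma::fill::zeros);
    arma::vec grad = pbar - e;
    for (int cyc = 0; cyc < 200; ++cyc) {
      double inner_max = 0.0;
      for (arma::uword j = 0; j < J; ++j) {
        double a = H(j, j);
        double old = delta(j), u;
        if (a < 1e-10) {
          u = lambda(j);
          if (std::fabs(grad(j)) > beta(j))
            u = lambda(j) + (grad(j) > 0 ? 1.0 : -1.0);
        } else {
          double g = grad(j) - Hd(j) + a * old;
          u = soft(lambda(j) + g / a, beta(j) / a);
        }
        double nd = u - lambda(j);
        if (nd > 5.0) nd = 5.0;
        if (nd < -5.0) nd = -5.0;
        double ch = nd - old;
        if (ch != 0.0) {
          delta(j) = nd;
          Hd += ch * H.col(j);
          if (std::fabs(ch) > inner_max) inner_max = std::fabs(ch);
        }
      }
      if (inner_max < 0.01 * tol) break;
    }

    double step_norm = arma::abs(delta).max();
    if (step_norm == 0.0) { max_update = 0.0; ++iter; break; }

    // backtracking line search on the true penalized objective
    arma::vec eta_step = F * delta;
    double alpha = 1.0;
    bool accepted = false;
    arma::vec lam_try, eta_try;
    double new_obj = obj;
    for (int bt = 0; bt < 30; ++bt) {
      lam_try = lambda + alpha * delta;
      eta_try = eta + alpha * eta_step;
      new_obj = obj_value(eta_try, pbar, beta, lam_try);
      if (new_obj >= obj - 1e-12) { accepted = true; break; }
      alpha *= 0.5;
    }
    if (!accepted) { max_update = 0.0; ++iter; break; }
    lambda = lam_try; eta = eta_try; obj = new_obj;
    max_update = alpha * step_norm;
    if (max_update < tol) { ++iter; break; }
  }

  // final raw distribution and entropy
  arma::vec w = arma::exp(eta - eta.max());
  double Z = arma::accu(w);
  arma::vec raw = w / Z;
  double Hent = 0.0;
  for (arma::uword i = 0; i < n; ++i)
    if (raw(i) > 0) Hent -= raw(i) * std::log(raw(i));
  double log_z = std::log(Z) + eta.max();
  return List::create(
    _["lambda"] = NumericVector(lambda.begin(), lambda.end()),
    _["raw"] = NumericVector(raw.begin(), raw.end()),
    _["entropy"] = Hent, _["log_z"] = log_z, _["objective"] = obj,
    _["iterations"] = iter, _["final_delta"] = max_update,
    _["converged"] = max_update < tol);
}
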