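#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Block coordinate-descent graphical lasso (Friedman-Hastie-Tibshirani),
// penalising off-diagonal precision entries only, so the working covariance
// keeps diag(W) = diag(S). Lambdas must be sorted decreasing; the lasso
// coefficients B are warm-started along the path.
//
// Convergence: mean absolute change of the off-diagonal working covariance
// below tol * mean(|S_offdiag|), the criterion the reference Fortran solver
// uses. Off-diagonal precision entries with |theta| < zero_tol are snapped
// to exact zero so the edge count is well defined under floating point.
// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     const double tol, const int max_sweeps,
                     const double zero_tol) {
  const int p = S.n_rows;
  const int nl = lambdas.n_elem;

  arma::mat W = S;                          // working covariance
  arma::mat B(p, p, arma::fill::zeros);     // B(k, j): lasso coefs, column j
  arma::cube thetas(p, p, nl);
  arma::vec ll0(nl);                        // log det(Theta) - tr(S Theta)
  arma::vec last_change(nl);
  IntegerVector converged(nl);

  double soff = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) soff += std::fabs(S(i, j));
  soff /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(soff, 1e-12);

  for (int il = 0; il < nl; ++il) {
    const double lam = lambdas(il);
    bool done = false;
    double avgdiff = 0.0;

    for (int sweep = 0; sweep < max_sweeps && !done; ++sweep) {
      avgdiff = 0.0;
      for (int j = 0; j < p; ++j) {
        // inner lasso: min 0.5 b' W11 b - s12' b + lam ||b||_1
        for (int inner = 0; inner < 500; ++inner) {
          double del = 0.0;
          for (int k = 0; k < p; ++k) {
            if (k == j) continue;
            double r = S(k, j);
            for (int l = 0; l < p; ++l) {
              if (l == j || l == k) continue;
              r -= W(k, l) * B(l, j);
            }
            double bnew = 0.0;
            if (r > lam) bnew = (r - lam) / W(k, k);
            else if (r < -lam) bnew = (r + lam) / W(k, k);
            const double d = std::fabs(bnew - B(k, j));
            if (d > del) del = d;
            B(k, j) = bnew;
          }
          if (del < 1e-10) break;
        }
        // update covariance column: w12 = W11 beta
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double v = 0.0;
          for (int l = 0; l < p; ++l) {
            if (l == j) continue;
            v += W(k, l) * B(l, j);
          }
          avgdiff += std::fabs(v - W(k, j));
          W(k, j) = v;
          W(j, k) = v;
        }
      }
      avgdiff /= std::max(1, p * (p - 1));
      if (avgdiff < thr) done = true;
    }
    converged(il) = done ? 1 : 0;
    last_change(il) = avgdiff;

    // recover Theta from (W, B): theta_jj = 1/(w_jj - w12' beta_j)
    arma::mat Th(p, p, arma::fill::zeros);
    for (int j = 0; j < p; ++j) {
      double q = W(j, j);
      for (int k = 0; k < p; ++k)
        if (k != j) q -= W(k, j) * B(k, j);
      const double tjj = 1.0 / q;
      Th(j, j) = tjj;
      for (int k = 0; k < p; ++k)
        if (k != j) Th(k, j) = -B(k, j) * tjj;
    }
    Th = 0.5 * (Th + Th.t());
    for (int j = 0; j < p; ++j)
      for (int k = 0; k < p; ++k)
        if (j != k && std::fabs(Th(k, j)) < zero_tol) Th(k, j) = 0.0;

    double ld, sign;
    arma::log_det(ld, sign, Th);
    ll0(il) = ld - arma::accu(S % Th);
    thetas.slice(il) = Th;
  }

  return List::create(_["theta"] = thetas,
                      _["ll0"] = ll0,
                      _["converged"] = converged,
                      _["last_change"] = last_change);
}

// Same path solver, but scores each fit by EBIC(n, gamma) in place and
// returns only the selected precision matrix. Lambdas sorted decreasing, so
// with which-min semantics EBIC ties resolve toward the sparser model.
// [[Rcpp::export]]
List glasso_ebic_cpp(const arma::mat& S, const arma::vec& lambdas,
                     const double n, const double gamma,
                     const double tol, const int max_sweeps,
                     const double zero_tol) {
  const int p = S.n_rows;
  const int nl = lambdas.n_elem;

  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  arma::mat Th(p, p, arma::fill::zeros);
  arma::mat best_theta(p, p, arma::fill::zeros);
  arma::vec ebics(nl);
  double best = R_PosInf;
  int best_idx = -1;
  const double logp4g = 4.0 * gamma * std::log((double) p);
  const double logn = std::log(n);

  double soff = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) soff += std::fabs(S(i, j));
  soff /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(soff, 1e-12);

  for (int il = 0; il < nl; ++il) {
    const double lam = lambdas(il);
    bool done = false;
    double avgdiff = 0.0;
    for (int sweep = 0; sweep < max_sweeps && !done; ++sweep) {
      avgdiff = 0.0;
      for (int j = 0; j < p; ++j) {
        for (int inner = 0; inner < 500; ++inner) {
          double del = 0.0;
          for (int k = 0; k < p; ++k) {
            if (k == j) continue;
            double r = S(k, j);
            for (int l = 0; l < p; ++l) {
              if (l == j || l == k) continue;
              r -= W(k, l) * B(l, j);
            }
            double bnew = 0.0;
            if (r > lam) bnew = (r - lam) / W(k, k);
            else if (r < -lam) bnew = (r + lam) / W(k, k);
            const double d = std::fabs(bnew - B(k, j));
            if (d > del) del = d;
            B(k, j) = bnew;
          }
          if (del < 1e-10) break;
        }
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double v = 0.0;
          for (int l = 0; l < p; ++l) {
            if (l == j) continue;
            v += W(k, l) * B(l, j);
          }
          avgdiff += std::fabs(v - W(k, j));
          W(k, j) = v;
          W(j, k) = v;
        }
      }
      avgdiff /= std::max(1, p * (p - 1));
      if (avgdiff < thr) done = true;
    }
    if (!done) stop("graphical lasso did not converge at lambda = %g", lam);

    int E = 0;
    for (int j = 0; j < p; ++j) {
      double q = W(j, j);
      for (int k = 0; k < p; ++k)
        if (k != j) q -= W(k, j) * B(k, j);
      const double tjj = 1.0 / q;
      Th(j, j) = tjj;
      for (int k = 0; k < p; ++k)
        if (k != j) Th(k, j) = -B(k, j) * tjj;
    }
    Th = 0.5 * (Th + Th.t());
    for (int j = 1; j < p; ++j)
      for (int k = 0; k < j; ++k) {
        if (std::fabs(Th(k, j)) < zero_tol) {
          Th(k, j) = 0.0; Th(j, k) = 0.0;
        } else ++E;
      }
    double ld, sign;
    arma::log_det(ld, sign, Th);
    const double eb = -n * (ld - arma::accu(S % Th)) + E * (logn + logp4g);
    ebics(il) = eb;
    if (eb < best) { best = eb; best_idx = il; best_theta = Th; }
  }

  return List::create(_["theta"] = best_theta,
                      _["lambda"] = lambdas(best_idx),
                      _["ebic"] = best,
                      _["ebic_path"] = ebics,
                      _["index"] = best_idx + 1);
}
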