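// Linear-Gaussian state-space machinery shared by the RW and CRW track models.
// Time-varying system matrices handle irregular sampling; observation rows of
// all-NA are treated as prediction-only time points (no update), which is how
// the regular-step prediction grid is realized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline arma::mat symm(const arma::mat& A) {
  return 0.5 * (A + A.t());
}

// Kalman filter + RTS smoother.
// y: n x p (NA rows = missing), Tm/Qm: m x m x (n-1), H: p x m, Rm: p x p x n,
// a0: m, P0: m x m.
// [[Rcpp::export(name = ".kalman_smooth")]]
List kalman_smooth(const arma::mat& y, const arma::cube& Tm,
                   const arma::cube& Qm, const arma::mat& H,
                   const arma::cube& Rm, const arma::vec& a0,
                   const arma::mat& P0) {
  const arma::uword n = y.n_rows, p = y.n_cols, m = a0.n_elem;
  arma::mat apred(m, n), afilt(m, n);
  arma::cube Ppred(m, m, n), Pfilt(m, m, n);
  arma::mat vstd(n, p); vstd.fill(NA_REAL);
  double loglik = 0.0;

  arma::vec a = a0;
  arma::mat P = P0;
  for (arma::uword t = 0; t < n; ++t) {
    if (t > 0) {
      const arma::mat Tt = Tm.slice(t - 1);
      a = Tt * a;
      P = symm(Tt * P * Tt.t() + Qm.slice(t - 1));
    }
    apred.col(t) = a;
    Ppred.slice(t) = P;
    const bool miss = !arma::is_finite(y.row(t));
    if (!miss) {
      const arma::vec v = y.row(t).t() - H * a;
      const arma::mat F = symm(H * P * H.t() + Rm.slice(t));
      arma::mat Fchol;
      if (!arma::chol(Fchol, F))
        stop("singular innovation covariance at observation %d", (int)(t + 1));
      const arma::vec w = arma::solve(arma::trimatl(Fchol.t()), v);
      loglik += -0.5 * (p * LOG2PI + 2.0 * arma::sum(arma::log(Fchol.diag())) +
                        arma::dot(w, w));
      vstd.row(t) = w.t();
      const arma::mat K = P * H.t() * arma::inv_sympd(F);
      a = a + K * v;
      P = symm(P - K * H * P);
    }
    afilt.col(t) = a;
    Pfilt.slice(t) = P;
  }

  // RTS backward pass
  arma::mat ahat(m, n);
  arma::cube Phat(m, m, n);
  ahat.col(n - 1) = afilt.col(n - 1);
  Phat.slice(n - 1) = Pfilt.slice(n - 1);
  for (arma::uword t = n - 1; t-- > 0;) {
    const arma::mat Tt = Tm.slice(t);
    const arma::mat Pp = Ppred.slice(t + 1);
    const arma::mat J = Pfilt.slice(t) * Tt.t() * arma::inv_sympd(symm(Pp));
    ahat.col(t) = afilt.col(t) + J * (ahat.col(t + 1) - apred.col(t + 1));
    Phat.slice(t) =
        symm(Pfilt.slice(t) + J * (Phat.slice(t + 1) - Pp) * J.t());
  }

  return List::create(_["loglik"] = loglik, _["ahat"] = ahat.t(),
                      _["Phat"] = Phat, _["afilt"] = afilt.t(),
                      _["Pfilt"] = Pfilt, _["apred"] = apred.t(),
                      _["Ppred"] = Ppred, _["vstd"] = vstd);
}

// Forward-filter backward-sampling draws from the joint smoothing distribution.
// Returns cube n x m x nsim. Uses R's RNG.
// [[Rcpp::export(name = ".kalman_ffbs")]]
arma::cube kalman_ffbs(const arma::mat& y, const arma::cube& Tm,
                       const arma::cube& Qm, const arma::mat& H,
                       const arma::cube& Rm, const arma::vec& a0,
                       const arma::mat& P0, const int nsim) {
  const arma::uword n = y.n_rows, m = a0.n_elem;
  arma::mat afilt(m, n);
  arma::cube Pfilt(m, m, n);
  arma::vec a = a0;
  arma::mat P = P0;
  for (arma::uword t = 0; t < n; ++t) {
    if (t > 0) {
      const arma::mat Tt = Tm.slice(t - 1);
      a = Tt * a;
      P = symm(Tt * P * Tt.t() + Qm.slice(t - 1));
    }
    if (arma::is_finite(y.row(t))) {
      const arma::mat F = symm(H * P * H.t() + Rm.slice(t));
      const arma::mat K = P * H.t() * arma::inv_sympd(F);
      a = a + K * (y.row(t).t() - H * a);
      P = symm(P - K * H * P);
    }
    afilt.col(t) = a;
    Pfilt.slice(t) = P;
  }

  arma::cube out(n, m, nsim);
  RNGScope scope;
  for (int s = 0; s < nsim; ++s) {
    arma::vec z(m);
    // draw s_n
    arma::mat C;
    arma::mat Pn = symm(Pfilt.slice(n - 1));
    if (!arma::chol(C, Pn + 1e-12 * arma::eye(m, m), "lower"))
      stop("filtered covariance not positive definite");
    for (arma::uword k = 0; k < m; ++k) z(k) = R::norm_rand();
    arma::vec x = afilt.col(n - 1) + C * z;
    out.slice(s).row(n - 1) = x.t();
    for (arma::uword t = n - 1; t-- > 0;) {
      const arma::mat Tt = Tm.slice(t);
      const arma::mat Pp =
          symm(Tt * Pfilt.slice(t) * Tt.t() + Qm.slice(t));
      const arma::mat J = Pfilt.slice(t) * Tt.t() * arma::inv_sympd(Pp);
      const arma::vec mu =
          afilt.col(t) + J * (x - Tt * afilt.col(t));
      const arma::mat S = symm(Pfilt.slice(t) - J * Tt * Pfilt.slice(t));
      if (!arma::chol(C, S + 1e-12 * arma::eye(m, m), "lower"))
        stop("conditional covariance not positive definite");
      for (arma::uword k = 0; k < m; ++k) z(k) = R::norm_rand();
      x = mu + C * z;
      out.slice(s).row(t) = x.t();
    }
  }
  return out;
}
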