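// Profiled maximum-likelihood estimation of the Gaussian linear mixed
// model with a single random intercept per group,
//   y = X beta + Z b + e,  b ~ N(0, sigma2 * theta),  e ~ N(0, sigma2 I),
// for many response vectors sharing one design. With V = I + theta Z Z'
// the profiled deviance in theta is
//   -2 l(theta) = n log(2 pi RSS*/n) + sum_i log(1 + theta n_i) + n,
// where RSS* is the GLS residual sum of squares. Because
// (I + theta ZZ')^{-1} = I - Z diag(w) Z' with w_i = theta/(1+theta n_i),
// every quantity reduces to the sufficient statistics X'X, X'Z, X'Y,
// Z'Y, y'y, so a deviance evaluation costs O(p^2 g + p^3) independent of
// the number of trials. theta is profiled per timepoint by a coarse grid
// on log(theta) (shared factorisations across timepoints) followed by
// golden-section refinement; the theta = 0 boundary (OLS) is evaluated
// exactly.
//
// Numerical care: as theta grows, columns of X that are constant within
// groups (the intercept, between-participant covariates) lose almost all
// information in the V-metric and A = X'V^{-1}X becomes severely
// ill-conditioned, which makes the Schur complement q - b'A^{-1}b
// cancel catastrophically. The normal equations are therefore solved
// after Jacobi (diagonal) scaling, which keeps the scaled A close to a
// well-conditioned correlation matrix, and the residual sum of squares
// is floored at a small multiple of q.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct SuffStat {
  arma::mat XtX, XtZ, XtY, ZtY;
  arma::vec yty, ng;
  double n;
};

struct Fact {
  arma::mat R;    // cholesky of the Jacobi-scaled A
  arma::vec d;    // scaling: sqrt(diag(A))
  bool ok;
};

inline Fact factor_A(const SuffStat& S, double theta) {
  Fact f;
  const arma::vec w = theta / (1.0 + theta * S.ng);
  arma::mat A = S.XtX - S.XtZ * arma::diagmat(w) * S.XtZ.t();
  f.d = arma::sqrt(A.diag());
  f.ok = f.d.is_finite() && arma::all(f.d > 0);
  if (!f.ok) return f;
  A.each_col() /= f.d;
  A.each_row() /= f.d.t();
  f.ok = arma::chol(f.R, A);
  return f;
}

inline double dev_at(const SuffStat& S, const Fact& F, double theta,
                     arma::uword t) {
  const arma::vec w = theta / (1.0 + theta * S.ng);
  arma::vec b = S.XtY.col(t) - S.XtZ * (w % S.ZtY.col(t));
  b /= F.d;
  double q = S.yty(t) - arma::dot(w, arma::square(S.ZtY.col(t)));
  arma::vec u = arma::solve(arma::trimatl(F.R.t()), b);
  double rss = q - arma::dot(u, u);
  const double floor_q = 1e-13 * std::max(q, 1e-300);
  if (rss < floor_q) rss = floor_q;
  double logdet = arma::accu(arma::log1p(theta * S.ng));
  return S.n * std::log(2.0 * M_PI * rss / S.n) + logdet + S.n;
}

inline double dev_solo(const SuffStat& S, double theta, arma::uword t,
                       bool& ok) {
  Fact f = factor_A(S, theta);
  if (!f.ok) { ok = false; return arma::datum::inf; }
  return dev_at(S, f, theta, t);
}

} // namespace

// [[Rcpp::export]]
List ri_ml_profile_cpp(const arma::mat& XtX, const arma::mat& XtZ,
                       const arma::mat& XtY, const arma::mat& ZtY,
                       const arma::vec& yty, const arma::vec& ng,
                       const double n) {
  SuffStat S{XtX, XtZ, XtY, ZtY, yty, ng, n};
  const arma::uword T = XtY.n_cols;

  // log-theta grid: theta = variance ratio sigma_b^2 / sigma_e^2
  const double u_lo = -12.0, u_hi = 8.0, u_step = 0.5;
  const int G = static_cast<int>((u_hi - u_lo) / u_step) + 1;

  arma::vec best_dev(T), best_u(T);
  arma::uvec boundary(T, arma::fill::ones); // start at theta = 0

  // theta = 0 (OLS) baseline
  Fact F0 = factor_A(S, 0.0);
  if (!F0.ok) {
    return List::create(_["loglik"] = NumericVector(T, NA_REAL),
                        _["theta"] = NumericVector(T, NA_REAL),
                        _["ok"] = LogicalVector(T, false));
  }
  for (arma::uword t = 0; t < T; ++t) {
    best_dev(t) = dev_at(S, F0, 0.0, t);
    best_u(t) = -arma::datum::inf;
  }

  // grid scan (factorise once per theta, evaluate all timepoints)
  for (int g = 0; g < G; ++g) {
    const double u = u_lo + g * u_step;
    const double theta = std::exp(u);
    Fact F = factor_A(S, theta);
    if (!F.ok) continue;
    for (arma::uword t = 0; t < T; ++t) {
      const double d = dev_at(S, F, theta, t);
      if (std::isfinite(d) && d < best_dev(t)) {
        best_dev(t) = d;
        best_u(t) = u;
        boundary(t) = 0;
      }
    }
  }

  // golden-section refinement around the grid minimum
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  NumericVector loglik(T), theta_out(T);
  LogicalVector okout(T);
  for (arma::uword t = 0; t < T; ++t) {
    bool ok = true;
    double dmin = best_dev(t), umin = best_u(t);
    if (boundary(t) == 0) {
      double a = best_u(t) - u_step, b = best_u(t) + u_step;
      double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
      double f1 = dev_solo(S, std::exp(x1), t, ok);
      double f2 = dev_solo(S, std::exp(x2), t, ok);
      for (int it = 0; it < 40 && (b - a) > 1e-7; ++it) {
        if (f1 <= f2) {
          b = x2; x2 = x1; f2 = f1;
          x1 = b - gr * (b - a);
          f1 = dev_solo(S, std::exp(x1), t, ok);
        } else {
          a = x1; x1 = x2; f1 = f2;
          x2 = a + gr * (b - a);
          f2 = dev_solo(S, std::exp(x2), t, ok);
        }
      }
      const double uu = (f1 <= f2) ? x1 : x2;
      const double ff = std::min(f1, f2);
      if (std::isfinite(ff) && ff < dmin) { dmin = ff; umin = uu; }
    }
    loglik[t] = -0.5 * dmin;
    theta_out[t] = std::isfinite(umin) ? std::exp(umin) : 0.0;
    okout[t] = ok && std::isfinite(dmin);
  }
  return List::create(_["loglik"] = loglik, _["theta"] = theta_out,
                      _["ok"] = okout);
}
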