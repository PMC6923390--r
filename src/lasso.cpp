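#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L1-penalized logistic regression,
//   min_beta sum_i [-y_i log h_i - (1-y_i) log(1-h_i)] + lambda * ||beta||_1
// with an unpenalized intercept, solved by iteratively reweighted least
// squares with cyclic coordinate descent (soft thresholding) on the
// quadratic subproblem. Each outer iteration is safeguarded by step
// halving toward the previous iterate, so the penalized objective is
// non-increasing across iterations. The reported iteration count and
// traced objective refer to outer (IRLS) iterations.

static inline double softthr(double u, double t) {
  if (u > t) return u - t;
  if (u < -t) return u + t;
  return 0.0;
}

static double objective(const std::vector<double>& eta, const NumericVector& y,
                        const std::vector<double>& beta, double lambda) {
  double obj = 0.0;
  const int n = (int)eta.size();
  for (int i = 0; i < n; ++i) {
    const double e = eta[i];
    obj += (e > 0 ? e : 0.0) - y[i] * e + std::log1p(std::exp(-std::fabs(e)));
  }
  for (size_t j = 0; j < beta.size(); ++j) obj += lambda * std::fabs(beta[j]);
  return obj;
}

static void computeEta(const NumericMatrix& X, const std::vector<double>& beta,
                       double b0, std::vector<double>& eta) {
  const int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) eta[i] = b0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double bj = beta[j];
      for (int i = 0; i < n; ++i) eta[i] += X(i, j) * bj;
    }
  }
}

// [[Rcpp::export]]
List cpp_lasso_cd(NumericMatrix X, NumericVector y, double lambda,
                  double tol, int max_iter, NumericVector beta0,
                  double intercept0, bool trace_obj) {
  const int n = X.nrow(), p = X.ncol();
  const double wfloor = 1e-5;
  std::vector<double> beta(p), betaOld(p);
  for (int j = 0; j < p; ++j) beta[j] = beta0[j];
  double b0 = intercept0;

  std::vector<double> eta(n), w(n), z(n), resid(n);
  computeEta(X, beta, b0, eta);
  double obj = objective(eta, y, beta, lambda);

  std::vector<double> objs;
  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // weighted least-squares working data at the current iterate
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-eta[i]));
      double wi = pr * (1.0 - pr);
      if (wi < wfloor) wi = wfloor;
      w[i] = wi;
      z[i] = eta[i] + (y[i] - pr) / wi;
      resid[i] = z[i] - eta[i];
    }
    betaOld = beta;
    const double b0Old = b0;

    std::vector<double> wx2(p);
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
      wx2[j] = s;
    }
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) wsum += w[i];

    // inner CD on the penalized quadratic; resid tracks z - current fit.
    // Full sweeps only to refresh the active (nonzero) set, which carries
    // the bulk of the iteration.
    const double innerTol = 0.1 * tol;
    auto updateCoord = [&](int j) -> double {
      if (wx2[j] <= 0.0) return 0.0;
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += w[i] * X(i, j) * resid[i];
      const double u = beta[j] + g / wx2[j];
      const double bnew = softthr(u, lambda / wx2[j]);
      const double d = bnew - beta[j];
      if (d != 0.0) {
        beta[j] = bnew;
        for (int i = 0; i < n; ++i) resid[i] -= X(i, j) * d;
      }
      return std::fabs(d);
    };
    auto updateIntercept = [&]() -> double {
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += w[i] * resid[i];
      const double d = g / wsum;
      if (d != 0.0) {
        b0 += d;
        for (int i = 0; i < n; ++i) resid[i] -= d;
      }
      return std::fabs(d);
    };
    for (int pass = 0; pass < 5; ++pass) {
      double maxd = updateIntercept();
      std::vector<int> active;
      for (int j = 0; j < p; ++j) { // full sweep refreshes the active set
        maxd = std::max(maxd, updateCoord(j));
        if (beta[j] != 0.0) active.push_back(j);
      }
      if (maxd < innerTol) break;
      for (int sweep = 0; sweep < 100; ++sweep) {
        double md = updateIntercept();
        for (size_t a = 0; a < active.size(); ++a)
          md = std::max(md, updateCoord(active[a]));
        if (md < innerTol) break;
      }
    }

    // step-halving safeguard: never let the true objective increase
    computeEta(X, beta, b0, eta);
    double objNew = objective(eta, y, beta, lambda);
    for (int h = 0; h < 30 && objNew > obj + 1e-12; ++h) {
      for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + betaOld[j]);
      b0 = 0.5 * (b0 + b0Old);
      computeEta(X, beta, b0, eta);
      objNew = objective(eta, y, beta, lambda);
    }
    if (objNew > obj + 1e-12) { // no descent possible: restore and stop
      beta = betaOld;
      b0 = b0Old;
      computeEta(X, beta, b0, eta);
      if (trace_obj) objs.push_back(obj);
      converged = true;
      ++iter;
      break;
    }
    obj = objNew;
    if (trace_obj) objs.push_back(obj);

    double maxDelta = std::fabs(b0 - b0Old);
    for (int j = 0; j < p; ++j)
      maxDelta = std::max(maxDelta, std::fabs(beta[j] - betaOld[j]));
    if (maxDelta < tol) { converged = true; ++iter; break; }
  }

  NumericVector betaOut(p);
  for (int j = 0; j < p; ++j) betaOut[j] = beta[j];
  return List::create(_["beta"] = betaOut, _["intercept"] = b0,
                      _["iter"] = iter, _["converged"] = converged,
                      _["objective"] = wrap(objs));
}
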