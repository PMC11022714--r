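// Elastic-net penalized logistic regression by cyclic coordinate descent on
// the IRLS quadratic approximation, with warm starts along a descending
// lambda path, sequential strong-rule screening and a full KKT check.
// Objective (intercept unpenalized):
//   (1/n) sum_i [log(1+exp(eta_i)) - y_i * eta_i]
//     + lambda * (alpha * ||beta||_1 + (1-alpha)/2 * ||beta||_2^2)
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent pass over `work` on the weighted least-squares
// problem; returns the largest absolute coefficient change. r holds the
// residual of the working response about the current fit and is kept in
// sync incrementally.
static double cd_pass(const NumericMatrix &X, const std::vector<double> &w,
                      std::vector<double> &r, std::vector<double> &beta,
                      double &b0, double wsum,
                      const std::vector<double> &xwx,
                      const std::vector<int> &work,
                      double l1, double l2, int n) {
  double maxdiff = 0.0;
  for (size_t a = 0; a < work.size(); ++a) {
    int j = work[a];
    const double *xj = &X(0, j);
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
    num = num / n + xwx[j] * beta[j];
    double bj = soft(num, l1) / (xwx[j] + l2);
    double d = bj - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      beta[j] = bj;
      if (std::fabs(d) > maxdiff) maxdiff = std::fabs(d);
    }
  }
  double num0 = 0.0;
  for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
  double d0 = num0 / wsum;
  if (d0 != 0.0) {
    for (int i = 0; i < n; ++i) r[i] -= d0;
    b0 += d0;
    if (std::fabs(d0) > maxdiff) maxdiff = std::fabs(d0);
  }
  return maxdiff;
}

// IRLS + coordinate descent restricted to the feature set `work`;
// converges when the largest coefficient change across one reweighting
// falls below tol.
static bool irls_cd(const NumericMatrix &X, const NumericVector &y,
                    std::vector<double> &beta, double &b0,
                    const std::vector<int> &work,
                    double l1, double l2, double tol,
                    int max_outer, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n), prob(n), w(n), r(n), xwx(p);
  for (int outer = 0; outer < max_outer; ++outer) {
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0) {
        const double *xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta[i] += xj[i] * beta[j];
      }
    }
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      if (pi < 1e-5) pi = 1e-5;
      if (pi > 1.0 - 1e-5) pi = 1.0 - 1e-5;
      prob[i] = pi;
      w[i] = pi * (1.0 - pi);
      r[i] = (y[i] - prob[i]) / w[i];  // z - eta
      wsum += w[i];
    }
    for (size_t a = 0; a < work.size(); ++a) {
      int j = work[a];
      const double *xj = &X(0, j);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
      xwx[j] = s / n;
    }
    std::vector<double> beta_in = beta;
    double b0_in = b0;
    int sweeps = 0;
    double diff = cd_pass(X, w, r, beta, b0, wsum, xwx, work, l1, l2, n);
    ++sweeps;
    while (diff >= tol && sweeps < max_sweeps) {
      std::vector<int> active;
      for (size_t a = 0; a < work.size(); ++a)
        if (beta[work[a]] != 0.0) active.push_back(work[a]);
      while (sweeps < max_sweeps) {
        diff = cd_pass(X, w, r, beta, b0, wsum, xwx, active, l1, l2, n);
        ++sweeps;
        if (diff < tol) break;
      }
      diff = cd_pass(X, w, r, beta, b0, wsum, xwx, work, l1, l2, n);
      ++sweeps;
      if (diff < tol) break;
    }
    double outer_change = std::fabs(b0 - b0_in);
    for (size_t a = 0; a < work.size(); ++a) {
      double d = std::fabs(beta[work[a]] - beta_in[work[a]]);
      if (d > outer_change) outer_change = d;
    }
    if (outer_change < tol) return true;
  }
  return false;
}

// (1/n) X'(y - p) at the current estimate, the logistic score used for
// strong-rule screening and the KKT check.
static void logistic_grad(const NumericMatrix &X, const NumericVector &y,
                          const std::vector<double> &beta, double b0,
                          std::vector<double> &g) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> res(n);
  for (int i = 0; i < n; ++i) res[i] = b0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double *xj = &X(0, j);
      for (int i = 0; i < n; ++i) res[i] += xj[i] * beta[j];
    }
  }
  for (int i = 0; i < n; ++i)
    res[i] = y[i] - 1.0 / (1.0 + std::exp(-res[i]));
  for (int j = 0; j < p; ++j) {
    const double *xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * res[i];
    g[j] = s / n;
  }
}

// [[Rcpp::export(name = ".cd_enet_logistic")]]
List cd_enet_logistic(NumericMatrix X, NumericVector y, double alpha,
                      NumericVector lambdas, double tol = 1e-7,
                      int max_outer = 100, int max_sweeps = 10000) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix betas(p, nl);
  NumericVector intercepts(nl);
  LogicalVector converged(nl);

  std::vector<double> beta(p, 0.0), g(p);
  double ymean = 0.0;
  for (int i = 0; i < n; ++i) ymean += y[i];
  ymean /= n;
  double b0 = std::log(ymean / (1.0 - ymean));

  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;

  double lam_prev = -1.0;
  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha, l2 = lam * (1.0 - alpha);
    bool conv = false;
    if (alpha <= 0.0) {
      // ridge: no screening (every coefficient is active)
      conv = irls_cd(X, y, beta, b0, all, l1, l2, tol, max_outer,
                     max_sweeps);
    } else {
      // sequential strong rule at the warm start, then solve on the
      // screened set and verify the discarded zeros by a full KKT check
      logistic_grad(X, y, beta, b0, g);
      double thr = alpha * (lam_prev > 0 ? 2.0 * lam - lam_prev : lam)
        - 1e-12;
      std::vector<int> work;
      std::vector<char> in_work(p, 0);
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0 || std::fabs(g[j]) >= thr) {
          work.push_back(j);
          in_work[j] = 1;
        }
      }
      for (int round = 0; round < 20; ++round) {
        conv = irls_cd(X, y, beta, b0, work, l1, l2, tol, max_outer,
                       max_sweeps);
        logistic_grad(X, y, beta, b0, g);
        bool violation = false;
        for (int j = 0; j < p; ++j) {
          if (!in_work[j] && std::fabs(g[j]) > l1 + 1e-10) {
            work.push_back(j);
            in_work[j] = 1;
            violation = true;
          }
        }
        if (!violation) break;
      }
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    intercepts[l] = b0;
    converged[l] = conv;
    lam_prev = lam;
  }
  return List::create(_["beta"] = betas, _["intercept"] = intercepts,
                      _["converged"] = converged);
}

// Sliding-window minimum (or maximum) over a variable-width window defined
// by m/z distance: out[i] = min/max of v over {k : |mz[k]-mz[i]| <= h}.
// Monotonic-deque algorithm, O(n).
static std::vector<double> roll_extreme(const NumericVector &mz,
                                        const std::vector<double> &v,
                                        double h, bool take_min) {
  const int n = mz.size();
  std::vector<double> out(n);
  std::deque<int> dq;
  int lo = 0, hi = -1;
  for (int i = 0; i < n; ++i) {
    while (hi + 1 < n && mz[hi + 1] <= mz[i] + h) {
      ++hi;
      while (!dq.empty() &&
             (take_min ? v[dq.back()] >= v[hi] : v[dq.back()] <= v[hi]))
        dq.pop_back();
      dq.push_back(hi);
    }
    while (lo < n && mz[lo] < mz[i] - h) {
      if (!dq.empty() && dq.front() == lo) dq.pop_front();
      ++lo;
    }
    out[i] = v[dq.front()];
  }
  return out;
}

// Morphological opening baseline: rolling minimum then rolling maximum over
// +/- half_window (m/z units).
// [[Rcpp::export(name = ".opening_baseline")]]
NumericVector opening_baseline(NumericVector mz, NumericVector intensity,
                               double half_window) {
  const int n = mz.size();
  std::vector<double> v(intensity.begin(), intensity.end());
  std::vector<double> eroded = roll_extreme(mz, v, half_window, true);
  std::vector<double> opened = roll_extreme(mz, eroded, half_window, false);
  return NumericVector(opened.begin(), opened.end());
}
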