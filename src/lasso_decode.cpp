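#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coordinate-descent lasso on pre-centered data: minimizes
//   (1/2n) ||y - X b||^2 + lambda * sum_j |b_j|
// (glmnet's objective with standardize = FALSE). X is column-major
// ntr x m in `X`; b is overwritten in place. Full passes until the
// largest coefficient change falls below tol or maxit passes.
// Covariance-update form: CD passes work on the Gram matrix G = X'X and
// q = X'y, so a full pass costs O(m^2) independent of the training-set
// size. `s` maintains G b.
static void cd_lasso_gram(const std::vector<double> &G,
                          const std::vector<double> &q, int ntr, int m,
                          double lambda, double tol, int maxit,
                          std::vector<double> &b) {
  std::fill(b.begin(), b.end(), 0.0);
  std::vector<double> s(m, 0.0);
  double nlam = ntr * lambda;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < m; ++j) {
      double gjj = G[(size_t)j * m + j];
      if (gjj <= 0.0) continue;
      double rho = q[j] - s[j] + gjj * b[j];
      double bj = 0.0;
      if (rho > nlam) bj = (rho - nlam) / gjj;
      else if (rho < -nlam) bj = (rho + nlam) / gjj;
      double diff = bj - b[j];
      if (diff != 0.0) {
        const double *gj = &G[(size_t)j * m];
        for (int l = 0; l < m; ++l) s[l] += gj[l] * diff;
        b[j] = bj;
        double ad = std::fabs(diff);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) break;
  }
}

// Residual-update CD on centered data (used when ntr is small relative to
// m, where forming the Gram matrix would not pay off).
static void cd_lasso(const std::vector<double> &X, const std::vector<double> &y,
                     int ntr, int m, double lambda, double tol, int maxit,
                     std::vector<double> &b, std::vector<double> &resid) {
  if (ntr > 2 * m) { // Gram route
    std::vector<double> G((size_t)m * m), q(m);
    for (int j = 0; j < m; ++j) {
      const double *xj = &X[(size_t)j * ntr];
      double qj = 0.0;
      for (int i = 0; i < ntr; ++i) qj += xj[i] * y[i];
      q[j] = qj;
      for (int l = j; l < m; ++l) {
        const double *xl = &X[(size_t)l * ntr];
        double g = 0.0;
        for (int i = 0; i < ntr; ++i) g += xj[i] * xl[i];
        G[(size_t)j * m + l] = g;
        G[(size_t)l * m + j] = g;
      }
    }
    cd_lasso_gram(G, q, ntr, m, lambda, tol, maxit, b);
    return;
  }
  std::vector<double> znorm(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *xj = &X[(size_t)j * ntr];
    for (int i = 0; i < ntr; ++i) s += xj[i] * xj[i];
    znorm[j] = s / ntr;
  }
  std::fill(b.begin(), b.end(), 0.0);
  resid = y;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < m; ++j) {
      if (znorm[j] <= 0.0) continue;
      const double *xj = &X[(size_t)j * ntr];
      double rho = 0.0;
      for (int i = 0; i < ntr; ++i) rho += xj[i] * resid[i];
      rho = rho / ntr + znorm[j] * b[j];
      double bj = 0.0;
      if (rho > lambda) bj = (rho - lambda) / znorm[j];
      else if (rho < -lambda) bj = (rho + lambda) / znorm[j];
      double diff = bj - b[j];
      if (diff != 0.0) {
        for (int i = 0; i < ntr; ++i) resid[i] -= xj[i] * diff;
        b[j] = bj;
        double ad = std::fabs(diff);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) break;
  }
}

// Single lasso fit with intercept (data centered internally); coefficients
// returned on the original scale. Exposed for cross-checking against an
// independent solver.
// [[Rcpp::export]]
List cd_lasso_fit(NumericMatrix Xin, NumericVector yin, double lambda,
                  double tol = 1e-4, int maxit = 10000) {
  int n = Xin.nrow(), m = Xin.ncol();
  std::vector<double> X((size_t)n * m), y(n), b(m), resid;
  std::vector<double> xbar(m);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += yin[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) y[i] = yin[i] - ybar;
  for (int j = 0; j < m; ++j) {
    double mj = 0.0;
    for (int i = 0; i < n; ++i) mj += Xin(i, j);
    mj /= n;
    xbar[j] = mj;
    for (int i = 0; i < n; ++i) X[(size_t)j * n + i] = Xin(i, j) - mj;
  }
  cd_lasso(X, y, n, m, lambda, tol, maxit, b, resid);
  double icpt = ybar;
  for (int j = 0; j < m; ++j) icpt -= b[j] * xbar[j];
  return List::create(_["intercept"] = icpt,
                      _["beta"] = NumericVector(b.begin(), b.end()));
}

// Iterative random-subset decoding over all timepoints.
//   data: trials x channels x timepoints array (column-major), dims = (n,p,T)
//   y: per-trial target
//   subsets: n_iter x m matrix of 0-based channel indices
//   folds: n_iter x n matrix of fold labels 0..k-1
// Per timepoint and iteration the lasso is fit on each training fold and
// held-out predictions are pooled over folds; decodability is the Pearson
// correlation between pooled predictions and the true target, averaged
// over iterations. Pooled predictions with zero variance contribute r = 0
// (counted in the "n_zero_var" attribute).
// [[Rcpp::export]]
NumericVector decode_course_cpp(NumericVector data, IntegerVector dims,
                                NumericVector y, IntegerMatrix subsets,
                                IntegerMatrix folds, double lambda,
                                double tol = 1e-4, int maxit = 10000) {
  int n = dims[0], p = dims[1], T = dims[2];
  int n_iter = subsets.nrow(), m = subsets.ncol();
  if (folds.nrow() != n_iter || folds.ncol() != n)
    stop("folds must be n_iter x n_trials");
  int k = 0;
  for (int i = 0; i < n_iter * n; ++i) if (folds[i] + 1 > k) k = folds[i] + 1;
  const double *D = REAL(data);
  NumericVector r_t(T);
  int n_zero_var = 0;

  std::vector<double> Xtr, ytr, b(m), resid, pred(n), xbar(m);
  std::vector<int> tr_idx, te_idx;
  Xtr.reserve((size_t)n * m);
  ytr.reserve(n);

  double ysum = 0.0, yss = 0.0;
  for (int i = 0; i < n; ++i) ysum += y[i];
  double ymean = ysum / n;
  for (int i = 0; i < n; ++i) yss += (y[i] - ymean) * (y[i] - ymean);

  for (int t = 0; t < T; ++t) {
    const double *Dt = D + (size_t)t * n * p;
    double acc = 0.0;
    for (int it = 0; it < n_iter; ++it) {
      for (int f = 0; f < k; ++f) {
        tr_idx.clear(); te_idx.clear();
        for (int i = 0; i < n; ++i) {
          if (folds(it, i) == f) te_idx.push_back(i);
          else tr_idx.push_back(i);
        }
        int ntr = (int)tr_idx.size();
        if (ntr < 2 || te_idx.empty()) continue;
        Xtr.assign((size_t)ntr * m, 0.0);
        ytr.resize(ntr);
        double ybar = 0.0;
        for (int i = 0; i < ntr; ++i) ybar += y[tr_idx[i]];
        ybar /= ntr;
        for (int i = 0; i < ntr; ++i) ytr[i] = y[tr_idx[i]] - ybar;
        for (int j = 0; j < m; ++j) {
          const double *col = Dt + (size_t)subsets(it, j) * n;
          double mj = 0.0;
          for (int i = 0; i < ntr; ++i) mj += col[tr_idx[i]];
          mj /= ntr;
          xbar[j] = mj;
          double *dst = &Xtr[(size_t)j * ntr];
          for (int i = 0; i < ntr; ++i) dst[i] = col[tr_idx[i]] - mj;
        }
        cd_lasso(Xtr, ytr, ntr, m, lambda, tol, maxit, b, resid);
        for (size_t ii = 0; ii < te_idx.size(); ++ii) {
          int i = te_idx[ii];
          double v = ybar;
          for (int j = 0; j < m; ++j) {
            if (b[j] != 0.0)
              v += b[j] * (Dt[(size_t)subsets(it, j) * n + i] - xbar[j]);
          }
          pred[i] = v;
        }
      }
      // pooled correlation over all trials
      double pm = 0.0;
      for (int i = 0; i < n; ++i) pm += pred[i];
      pm /= n;
      double sp = 0.0, spy = 0.0;
      for (int i = 0; i < n; ++i) {
        double dp = pred[i] - pm;
        sp += dp * dp;
        spy += dp * (y[i] - ymean);
      }
      if (sp <= 0.0 || yss <= 0.0) {
        ++n_zero_var; // r contributes 0
      } else {
        acc += spy / std::sqrt(sp * yss);
      }
    }
    r_t[t] = acc / n_iter;
  }
  r_t.attr("n_zero_var") = n_zero_var;
  return r_t;
}
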