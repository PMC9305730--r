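#include <Rcpp.h>
using namespace Rcpp;

// One full EM run for the multinomial latent class model, starting from an
// initial responsibility matrix. Each iteration performs an M-step from the
// current responsibilities followed by an E-step; the log-likelihood recorded
// at iteration t belongs to the parameters produced by that M-step, so the
// trace is non-decreasing (up to the smoothing floor applied to the
// item-category probabilities).
//
// x:      N x J matrix of 1-based category codes (complete cases)
// ncat:   J category counts
// gamma0: N x K initial responsibilities (rows sum to 1)
// floor_: lower bound applied to item-category probabilities after each
//         M-step (renormalised); guards against -Inf holdout likelihoods
// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(IntegerMatrix x, IntegerVector ncat, NumericMatrix gamma0,
                double tol, int max_iter, double floor_) {
  const int n = x.nrow(), j = x.ncol(), k = gamma0.ncol();

  NumericMatrix gamma = clone(gamma0);
  NumericVector pi(k);
  std::vector<NumericMatrix> rho;          // per item: K x C_j
  std::vector<NumericMatrix> logrho;
  for (int jj = 0; jj < j; ++jj) {
    rho.push_back(NumericMatrix(k, ncat[jj]));
    logrho.push_back(NumericMatrix(k, ncat[jj]));
  }
  NumericVector logpi(k);
  std::vector<double> trace;
  bool converged = false;
  double ll_prev = R_NegInf;
  int iter = 0;
  bool empty_class = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- M-step from current responsibilities ----
    NumericVector gsum(k);
    for (int i = 0; i < n; ++i)
      for (int kk = 0; kk < k; ++kk) gsum[kk] += gamma(i, kk);
    for (int kk = 0; kk < k; ++kk) {
      if (gsum[kk] < 1e-8) empty_class = true;
      pi[kk] = gsum[kk] / n;
      logpi[kk] = std::log(std::max(pi[kk], 1e-300));
    }
    for (int jj = 0; jj < j; ++jj) {
      NumericMatrix &r = rho[jj];
      std::fill(r.begin(), r.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        const int c = x(i, jj) - 1;
        for (int kk = 0; kk < k; ++kk) r(kk, c) += gamma(i, kk);
      }
      NumericMatrix &lr = logrho[jj];
      for (int kk = 0; kk < k; ++kk) {
        double denom = std::max(gsum[kk], 1e-300);
        double s = 0.0;
        for (int c = 0; c < ncat[jj]; ++c) {
          double v = r(kk, c) / denom;
          if (v < floor_) v = floor_;
          r(kk, c) = v;
          s += v;
        }
        for (int c = 0; c < ncat[jj]; ++c) {
          r(kk, c) /= s;
          lr(kk, c) = std::log(r(kk, c));
        }
      }
    }

    // ---- E-step ----
    double ll = 0.0;
    std::vector<double> a(k);
    for (int i = 0; i < n; ++i) {
      double amax = R_NegInf;
      for (int kk = 0; kk < k; ++kk) {
        double s = logpi[kk];
        for (int jj = 0; jj < j; ++jj) s += logrho[jj](kk, x(i, jj) - 1);
        a[kk] = s;
        if (s > amax) amax = s;
      }
      double denom = 0.0;
      for (int kk = 0; kk < k; ++kk) denom += std::exp(a[kk] - amax);
      ll += amax + std::log(denom);
      for (int kk = 0; kk < k; ++kk)
        gamma(i, kk) = std::exp(a[kk] - amax) / denom;
    }
    trace.push_back(ll);

    if (iter > 1) {
      double rel = std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1e-10);
      if (rel < tol) { converged = true; break; }
    }
    ll_prev = ll;
  }

  List rho_out(j);
  for (int jj = 0; jj < j; ++jj) rho_out[jj] = rho[jj];
  return List::create(
    _["pi"] = pi,
    _["rho"] = rho_out,
    _["posteriors"] = gamma,
    _["loglik"] = trace.back(),
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["n_iter"] = std::min(iter, max_iter),
    _["empty_class"] = empty_class
  );
}
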