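#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted least-squares polynomial fit centered at q; returns fitted value
// at q (the intercept). Falls back to lower degree on a singular local
// system, and finally to the weighted mean.
static double local_fit(const arma::vec& xs, const arma::vec& ys,
                        const arma::vec& w, double q, int degree) {
  for (int deg = degree; deg >= 1; --deg) {
    arma::mat X(xs.n_elem, deg + 1);
    X.col(0).ones();
    for (int d = 1; d <= deg; ++d) X.col(d) = arma::pow(xs - q, d);
    arma::mat Xw = X.each_col() % w;
    arma::mat A = Xw.t() * X;
    arma::vec b = Xw.t() * ys;
    arma::vec beta;
    bool ok = arma::solve(beta, A, b, arma::solve_opts::no_approx);
    if (ok && beta.is_finite()) return beta(0);
  }
  double sw = arma::accu(w);
  if (sw > 0) return arma::dot(w, ys) / sw;
  return arma::mean(ys);
}

// Pointwise tricube-weighted local polynomial prediction.
// Neighborhood: the k = ceil(span * n) nearest training points by |x - q|,
// clamped to [degree + 2, n]; all points tied at the cutoff distance are
// included. Tricube weights w = (1 - (d/dmax)^3)^3 with dmax the largest
// selected distance. Queries outside [min(x), max(x)] return NA (the
// curves are never extrapolated).
// [[Rcpp::export]]
NumericVector loess_predict_cpp(NumericVector x, NumericVector y,
                                NumericVector xnew, double span, int degree) {
  const int n = x.size();
  double xmin = R_PosInf, xmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
  }
  int k = (int)std::ceil(span * n);
  if (k < degree + 2) k = degree + 2;
  if (k > n) k = n;

  const int m = xnew.size();
  NumericVector out(m);
  std::vector<double> d(n), ds(n);
  std::vector<int> idx;
  idx.reserve(n);

  for (int j = 0; j < m; ++j) {
    double q = xnew[j];
    if (!R_finite(q) || q < xmin || q > xmax) {
      out[j] = NA_REAL;
      continue;
    }
    for (int i = 0; i < n; ++i) d[i] = std::abs(x[i] - q);
    ds = d;
    std::nth_element(ds.begin(), ds.begin() + (k - 1), ds.end());
    const double dk = ds[k - 1];

    idx.clear();
    for (int i = 0; i < n; ++i)
      if (d[i] <= dk) idx.push_back(i);
    const int ns = (int)idx.size();

    if (dk <= 0.0) {  // all selected points sit exactly at q
      double s = 0.0;
      for (int i = 0; i < ns; ++i) s += y[idx[i]];
      out[j] = s / ns;
      continue;
    }

    arma::vec xs(ns), ys(ns), w(ns);
    bool all_zero = true;
    for (int i = 0; i < ns; ++i) {
      xs(i) = x[idx[i]];
      ys(i) = y[idx[i]];
      double u = d[idx[i]] / dk;
      double t = 1.0 - u * u * u;
      w(i) = t * t * t;
      if (w(i) > 0.0) all_zero = false;
    }
    if (all_zero) w.ones();  // every neighbor at the cutoff distance

    out[j] = local_fit(xs, ys, w, q, degree);
  }
  return out;
}
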