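#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// OLS + PRESS statistics for a design matrix that already includes the
// intercept column. Returns NA-filled output when the design is rank
// deficient or any leverage is numerically 1, so callers can treat the
// proposal as invalid instead of crashing.
// [[Rcpp::export]]
NumericVector cpp_ols_press(const arma::mat& X, const arma::vec& y) {
  NumericVector out = NumericVector::create(
      Named("loocv_rmse") = NA_REAL, Named("loocv_r2") = NA_REAL,
      Named("rss") = NA_REAL, Named("r2") = NA_REAL,
      Named("adj_r2") = NA_REAL);
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (n <= p) return out;
  arma::mat Q, R;
  if (!arma::qr_econ(Q, R, X)) return out;
  arma::vec d = arma::abs(R.diag());
  if (d.max() <= 0.0 || d.min() < 1e-10 * d.max()) return out;
  arma::vec qty = Q.t() * y;
  arma::vec resid = y - Q * qty;
  arma::vec h = arma::sum(arma::square(Q), 1);
  if (h.max() > 1.0 - 1e-10) return out;
  const double rss = arma::dot(resid, resid);
  const double ybar = arma::mean(y);
  const double sst = arma::accu(arma::square(y - ybar));
  arma::vec pr = resid / (1.0 - h);
  const double press = arma::dot(pr, pr);
  const double r2 = sst > 0.0 ? 1.0 - rss / sst : NA_REAL;
  out["loocv_rmse"] = std::sqrt(press / double(n));
  out["loocv_r2"] = sst > 0.0 ? 1.0 - press / sst : NA_REAL;
  out["rss"] = rss;
  out["r2"] = r2;
  if (sst > 0.0 && n > p)
    out["adj_r2"] = 1.0 - (1.0 - r2) * double(n - 1) / double(n - p);
  return out;
}
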