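// Zero-phase IIR filtering along the time axis of a signals x time
// matrix. The input is transposed once so each signal's samples are
// contiguous, then the direct-form-II-transposed recursion runs
// serially per signal entirely in cache.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline void df2t_pass(const arma::vec& b, const arma::vec& a,
                             double* x, const arma::uword n, bool reverse) {
  const arma::uword m = b.n_elem - 1;
  double z[16] = {0.0};
  for (arma::uword s = 0; s < n; ++s) {
    const arma::uword t = reverse ? n - 1 - s : s;
    const double xt = x[t];
    const double yt = b(0) * xt + z[0];
    for (arma::uword k = 0; k + 1 < m; ++k) {
      z[k] = z[k + 1] + b(k + 1) * xt - a(k + 1) * yt;
    }
    z[m - 1] = b(m) * xt - a(m) * yt;
    x[t] = yt;
  }
}

// [[Rcpp::export(name = ".cpp_filtfilt_cols")]]
arma::mat cpp_filtfilt_cols(const arma::vec& b, const arma::vec& a,
                            const arma::mat& X) {
  const arma::uword ns = X.n_rows, nt = X.n_cols;
  const arma::uword m = std::max(b.n_elem, a.n_elem) - 1;
  if (m > 15) Rcpp::stop("filter order too high");
  arma::vec bb(m + 1, arma::fill::zeros), aa(m + 1, arma::fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  bb /= aa(0);
  aa /= aa(0);
  const arma::uword pad = std::min<arma::uword>(3 * m, nt - 1);
  const arma::uword ntp = nt + 2 * pad;
  arma::mat T(ntp, ns);
  T.rows(pad, pad + nt - 1) = X.t();
  for (arma::uword j = 0; j < ns; ++j) {
    double* col = T.colptr(j);
    const double first = col[pad], last = col[pad + nt - 1];
    for (arma::uword k = 0; k < pad; ++k) {
      col[pad - 1 - k] = 2.0 * first - col[pad + k + 1];
      col[pad + nt + k] = 2.0 * last - col[pad + nt - 2 - k];
    }
    df2t_pass(bb, aa, col, ntp, false);
    df2t_pass(bb, aa, col, ntp, true);
  }
  return T.rows(pad, pad + nt - 1).t();
}
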