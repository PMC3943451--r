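#include <Rcpp.h>
using namespace Rcpp;

// Accumulate per-respondent log-likelihood over quadrature nodes.
// resp:   n x J integer matrix, collapsed responses 0..2, NA for missing
// rowidx: n x J integer matrix, 1-based row of the parameter table that
//         applies to respondent i on item j (split items vary by cell)
// logp:   R x 3 x Q array (vector, column-major) of log category
//         probabilities at each quadrature node
// [[Rcpp::export]]
NumericMatrix grm_loglik_mat(IntegerMatrix resp, IntegerMatrix rowidx,
                             NumericVector logp, int npar, int nq) {
  const int n = resp.nrow(), J = resp.ncol();
  NumericMatrix out(n, nq);
  const double *lp = logp.begin();
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < n; ++i) {
      int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      int r = rowidx(i, j) - 1;
      const double *base = lp + r + (size_t)npar * x;
      double *o = &out(i, 0);
      for (int q = 0; q < nq; ++q)
        o[(size_t)q * n] += base[(size_t)q * npar * 3];
    }
  }
  return out;
}

// Expected category counts per parameter row and node given posteriors.
// post: n x Q posterior weights; returns R x 3 x Q array (vector).
// [[Rcpp::export]]
NumericVector grm_expected_counts(IntegerMatrix resp, IntegerMatrix rowidx,
                                  NumericMatrix post, int npar) {
  const int n = resp.nrow(), J = resp.ncol(), nq = post.ncol();
  NumericVector out((size_t)npar * 3 * nq);
  double *o = out.begin();
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < n; ++i) {
      int x = resp(i, j);
      if (x == NA_INTEGER) continue;
      int r = rowidx(i, j) - 1;
      const double *p = &post(i, 0);
      double *base = o + r + (size_t)npar * x;
      for (int q = 0; q < nq; ++q)
        base[(size_t)q * npar * 3] += p[(size_t)q * n];
    }
  }
  return out;
}
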