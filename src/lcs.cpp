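#include <Rcpp.h>
using namespace Rcpp;

// Classic O(|a||b|) dynamic program over integer-encoded tokens.
// Two rolling rows keep memory at O(min side) scale for the matrix path.
static int lcs_int(const IntegerVector& a, const IntegerVector& b) {
  const int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  for (int i = 1; i <= na; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      cur[j] = (ai == b[j - 1]) ? prev[j - 1] + 1
                                : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector a, IntegerVector b) {
  return lcs_int(a, b);
}

// Pairwise LCS distance matrix over a list of integer-encoded sequences.
// norm: 0 = max-length, 1 = mean-length, 2 = sum-length denominator.
// [[Rcpp::export]]
NumericMatrix cpp_lcs_dist_matrix(List seqs, int norm) {
  const int n = seqs.size();
  std::vector<IntegerVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<IntegerVector>(seqs[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
    for (int j = i + 1; j < n; ++j) {
      const double L = lcs_int(s[i], s[j]);
      const double la = s[i].size(), lb = s[j].size();
      double denom;
      if (norm == 0)      denom = std::max(la, lb);
      else if (norm == 1) denom = (la + lb) / 2.0;
      else                denom = la + lb;
      const double d = 1.0 - L / denom;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
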