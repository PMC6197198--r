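#include <Rcpp.h>
#include <vector>
#include <stdexcept>
using namespace Rcpp;

// Exact hypergeometric tail probabilities by integer enumeration.
//
// For a 2x2 table (a, b, c, d) the population is N = a+b+c+d, the number of
// feature-positive intervals K = a+c, the number of case intervals n = a+b,
// and the observed overlap is a. The upper tail is
//   P(X >= a) = sum_{k >= a} C(K, k) C(N-K, n-k) / C(N, n)
// and the lower tail replaces k >= a by k <= a. All binomial coefficients
// are computed in 64-bit integers (exact up to N = 62: C(62,31) < 2^64) and
// the summation is carried in unsigned __int128, so the only rounding is the
// final long-double division.

// [[Rcpp::export]]
NumericVector hypergeom_tail_exact_cpp(IntegerVector a, IntegerVector b,
                                       IntegerVector c, IntegerVector d,
                                       LogicalVector lower) {
  R_xlen_t m = a.size();
  if (b.size() != m || c.size() != m || d.size() != m || lower.size() != m)
    stop("all arguments must have the same length");

  int maxN = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("table entries must be non-negative");
    int N = a[i] + b[i] + c[i] + d[i];
    if (N > 62) stop("exact enumeration supports N <= 62");
    if (N > maxN) maxN = N;
  }

  // Pascal's triangle, exact in unsigned 64-bit for N <= 62
  std::vector< std::vector<unsigned long long> > ch(maxN + 1);
  for (int i = 0; i <= maxN; ++i) {
    ch[i].assign(i + 1, 1ULL);
    for (int j = 1; j < i; ++j) ch[i][j] = ch[i - 1][j - 1] + ch[i - 1][j];
  }

  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    int N = a[i] + b[i] + c[i] + d[i];
    int K = a[i] + c[i];
    int n = a[i] + b[i];
    int lo = std::max(0, n - (N - K));
    int hi = std::min(n, K);
    unsigned __int128 num = 0;
    if (lower[i]) {
      for (int k = lo; k <= std::min(hi, a[i]); ++k)
        num += (unsigned __int128) ch[K][k] * ch[N - K][n - k];
    } else {
      for (int k = std::max(lo, a[i]); k <= hi; ++k)
        num += (unsigned __int128) ch[K][k] * ch[N - K][n - k];
    }
    unsigned __int128 den = (N >= n) ? (unsigned __int128) ch[N][n] : 1;
    out[i] = (double) ((long double) num / (long double) den);
  }
  return out;
}
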