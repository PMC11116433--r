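#include <Rcpp.h>
using namespace Rcpp;

// Valid-mode mean over every w x w patch via running sums along each axis.
// Pixel values here are small integers (level * 20), so the running sums
// are exact in double precision regardless of accumulation order.
// [[Rcpp::export(name = ".box_mean_valid")]]
NumericMatrix box_mean_valid(const NumericMatrix& x, const int w) {
  const int n = x.nrow(), m = x.ncol();
  if (w < 1 || w > n || w > m)
    stop("patch side outside the matrix extent");
  const int on = n - w + 1, om = m - w + 1;
  NumericMatrix tmp(on, m);   // moving sums down each column
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < w; ++i) s += x(i, j);
    tmp(0, j) = s;
    for (int i = w; i < n; ++i) {
      s += x(i, j) - x(i - w, j);
      tmp(i - w + 1, j) = s;
    }
  }
  // then along each row, traversing column-major with rolling row sums
  NumericMatrix out(on, om);
  const double ww = (double)(w * w);
  std::vector<double> s(on, 0.0);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < on; ++i) s[i] += tmp(i, j);
  for (int i = 0; i < on; ++i) out(i, 0) = s[i] / ww;
  for (int j = w; j < m; ++j) {
    for (int i = 0; i < on; ++i) {
      s[i] += tmp(i, j) - tmp(i, j - w);
      out(i, j - w + 1) = s[i] / ww;
    }
  }
  return out;
}
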