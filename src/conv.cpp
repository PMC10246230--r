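#include <Rcpp.h>
using namespace Rcpp;

// Separable 1-D convolution of a matrix along rows (axis 1) or columns
// (axis 2), zero padding. Used by the Canny edge detector, where small
// Gaussian/Sobel kernels make FFT-based filtering wasteful.
// [[Rcpp::export]]
NumericMatrix conv_sep(const NumericMatrix& m, const NumericVector& k,
                       const int axis) {
  const int nr = m.nrow(), nc = m.ncol(), nk = k.size();
  const int r = (nk - 1) / 2;
  NumericMatrix out(nr, nc);
  if (axis == 1) {
    for (int j = 0; j < nc; ++j) {
      const double* col = &m(0, j);
      double* o = &out(0, j);
      for (int i = 0; i < nr; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(nr - 1, i + r);
        for (int s = lo; s <= hi; ++s) acc += k[s - i + r] * col[s];
        o[i] = acc;
      }
    }
  } else {
    for (int j = 0; j < nc; ++j) {
      const int lo = std::max(0, j - r), hi = std::min(nc - 1, j + r);
      double* o = &out(0, j);
      for (int s = lo; s <= hi; ++s) {
        const double w = k[s - j + r];
        const double* col = &m(0, s);
        for (int i = 0; i < nr; ++i) o[i] += w * col[i];
      }
    }
  }
  return out;
}
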