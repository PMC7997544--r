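#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (half-sample) boundary reflection: ..., x[1], x[0] | x[0], x[1], ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 1-D convolution of a 3-D array along one dimension with an odd-length
// kernel, reflective boundaries. dims = (d1, d2, d3), column-major as in R.
// Lines along the target dimension are copied into a reflected buffer and
// convolved with a tight inner loop.
static void conv_along(const double* in, double* out,
                       int d1, int d2, int d3,
                       const double* ker, int klen, int dim) {
  int r = klen / 2;
  int n = (dim == 1) ? d1 : (dim == 2) ? d2 : d3;
  size_t stride = (dim == 1) ? 1 : (dim == 2) ? (size_t)d1
                                              : (size_t)d1 * d2;
  int o1 = (dim == 1) ? d2 : d1;
  int o2 = (dim == 3) ? d2 : d3;
  size_t s1 = (dim == 1) ? (size_t)d1 : 1;
  size_t s2 = (dim == 3) ? (size_t)d1 : (size_t)d1 * d2;
  std::vector<double> buf(n + 2 * r);
  for (int b = 0; b < o2; ++b) {
    for (int a = 0; a < o1; ++a) {
      const double* src = in + (size_t)a * s1 + (size_t)b * s2;
      double* dst = out + (size_t)a * s1 + (size_t)b * s2;
      for (int i = 0; i < n; ++i) buf[r + i] = src[(size_t)i * stride];
      for (int i = 0; i < r; ++i) {
        buf[i] = buf[r + reflect(i - r, n)];
        buf[n + r + i] = buf[r + reflect(n + i, n)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double* bp = &buf[i];
        for (int t = 0; t < klen; ++t) acc += ker[t] * bp[t];
        dst[(size_t)i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector sep_conv3_cpp(NumericVector x, IntegerVector dims,
                            NumericVector k1, NumericVector k2,
                            NumericVector k3) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  NumericVector out(x.size());
  std::vector<double> tmp(n);
  conv_along(REAL(x), tmp.data(), d1, d2, d3, REAL(k1), k1.size(), 1);
  conv_along(tmp.data(), REAL(out), d1, d2, d3, REAL(k2), k2.size(), 2);
  if (k3.size() > 1) {
    std::copy(REAL(out), REAL(out) + n, tmp.data());
    conv_along(tmp.data(), REAL(out), d1, d2, d3, REAL(k3), k3.size(), 3);
  } else {
    for (size_t i = 0; i < n; ++i) out[i] *= k3[0];
  }
  out.attr("dim") = dims;
  return out;
}

// Dense correlation with an arbitrary odd-dimension 3-D kernel (used for
// non-separable PSFs). Convolution = correlation with the flipped kernel;
// the caller flips when convolution semantics are required.
// [[Rcpp::export]]
NumericVector corr3_cpp(NumericVector x, IntegerVector dims,
                        NumericVector ker, IntegerVector kdims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int q1 = kdims[0], q2 = kdims[1], q3 = kdims[2];
  int r1 = q1 / 2, r2 = q2 / 2, r3 = q3 / 2;
  NumericVector out(x.size());
  const double* in = REAL(x);
  const double* kk = REAL(ker);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double acc = 0.0;
        for (int c = 0; c < q3; ++c) {
          int zz = reflect(k + c - r3, d3);
          for (int b = 0; b < q2; ++b) {
            int jj = reflect(j + b - r2, d2);
            for (int a = 0; a < q1; ++a) {
              int ii = reflect(i + a - r1, d1);
              acc += kk[(size_t)c * q1 * q2 + (size_t)b * q1 + a] *
                     in[(size_t)zz * d1 * d2 + (size_t)jj * d1 + ii];
            }
          }
        }
        out[(size_t)k * d1 * d2 + (size_t)j * d1 + i] = acc;
      }
  out.attr("dim") = dims;
  return out;
}
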