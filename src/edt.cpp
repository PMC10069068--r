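#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform on a sampled grid with spacing h
// (lower envelope of parabolas, Felzenszwalb & Huttenlocher 2012).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      double num = (f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k]);
      s = num / (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector voxel) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(mask.size());
  // distance to the nearest background (FALSE) voxel center, 0 on background
  for (R_xlen_t i = 0; i < mask.size(); i++) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // axis 1
  f.resize(d1); d.resize(d1);
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++) {
      const R_xlen_t base = (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
      for (int i = 0; i < d1; i++) f[i] = out[base + i];
      dt1d(f, d, d1, voxel[0]);
      for (int i = 0; i < d1; i++) out[base + i] = d[i];
    }
  // axis 2
  f.resize(d2); d.resize(d2);
  for (int k = 0; k < d3; k++)
    for (int i = 0; i < d1; i++) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * d1 * d2;
      for (int j = 0; j < d2; j++) f[j] = out[base + (R_xlen_t)j * d1];
      dt1d(f, d, d2, voxel[1]);
      for (int j = 0; j < d2; j++) out[base + (R_xlen_t)j * d1] = d[j];
    }
  // axis 3
  f.resize(d3); d.resize(d3);
  for (int j = 0; j < d2; j++)
    for (int i = 0; i < d1; i++) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * d1;
      for (int k = 0; k < d3; k++) f[k] = out[base + (R_xlen_t)k * d1 * d2];
      dt1d(f, d, d3, voxel[2]);
      for (int k = 0; k < d3; k++) out[base + (R_xlen_t)k * d1 * d2] = d[k];
    }
  for (R_xlen_t i = 0; i < out.size(); i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}
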