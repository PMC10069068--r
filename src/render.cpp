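#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rendering primitives. All coordinates are physical micrometres in array
// axis order (a1, a2, a3); voxel centers sit at (index - 0.5) * voxel_size
// (1-based R indices). Painters modify `vol` in place (the callers own a
// freshly allocated array) and combine intensities with max().

static inline R_xlen_t lin(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)j * d1 + (R_xlen_t)k * (R_xlen_t)d1 * d2;
}

static inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

// distance from p to segment a-b; t_out in [0,1] is the projection parameter
static double seg_dist(const double* p, const double* a, const double* b,
                       double& t_out) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double L2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = L2 > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / L2 : 0.0;
  t = clamp01(t);
  double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
  t_out = t;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// mode 0: filled tube, soft edge of width `width`
// mode 1: Gaussian shell ridge at radius (r - offset), sd `width`
//' @noRd
// [[Rcpp::export(name = ".paint_tube_cpp")]]
void paint_tube_cpp(NumericVector vol, IntegerVector dim, NumericVector voxel,
                    NumericMatrix poly, NumericVector radii, int mode,
                    double offset, double width, double amp) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double v1 = voxel[0], v2 = voxel[1], v3 = voxel[2];
  for (int s = 0; s + 1 < poly.nrow(); s++) {
    double a[3] = {poly(s, 0), poly(s, 1), poly(s, 2)};
    double b[3] = {poly(s + 1, 0), poly(s + 1, 1), poly(s + 1, 2)};
    double r0 = radii[s], r1 = radii[s + 1];
    double rmax = std::max(r0, r1);
    double margin = rmax + 4.0 * width + std::abs(offset);
    int i0 = std::max(0, (int)std::floor((std::min(a[0], b[0]) - margin) / v1));
    int i1 = std::min(d1 - 1, (int)std::ceil((std::max(a[0], b[0]) + margin) / v1));
    int j0 = std::max(0, (int)std::floor((std::min(a[1], b[1]) - margin) / v2));
    int j1 = std::min(d2 - 1, (int)std::ceil((std::max(a[1], b[1]) + margin) / v2));
    int k0 = std::max(0, (int)std::floor((std::min(a[2], b[2]) - margin) / v3));
    int k1 = std::min(d3 - 1, (int)std::ceil((std::max(a[2], b[2]) + margin) / v3));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double p[3] = {(i + 0.5) * v1, (j + 0.5) * v2, (k + 0.5) * v3};
          double t, d = seg_dist(p, a, b, t);
          double r = r0 + (r1 - r0) * t;
          double I;
          if (mode == 0) {
            I = amp * clamp01(0.5 + (r - d) / width);
          } else {
            double dd = d - (r - offset);
            I = amp * std::exp(-dd * dd / (2.0 * width * width));
          }
          R_xlen_t q = lin(i, j, k, d1, d2);
          if (I > vol[q]) vol[q] = I;
        }
  }
}

// Wall-marker shell over a whole network: a Gaussian ridge centered at
// (local radius - offset) from the centerline, computed on the minimum
// distance field over ALL segments of all polylines. (Painting shells per
// segment would add spherical end-caps at every joint whose union fills
// the tube interior.)
//' @noRd
// [[Rcpp::export(name = ".paint_shell_cpp")]]
void paint_shell_cpp(NumericVector vol, IntegerVector dim, NumericVector voxel,
                     List polys, List radii, double offset, double width,
                     double amp) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double v1 = voxel[0], v2 = voxel[1], v3 = voxel[2];
  const R_xlen_t n = vol.size();
  std::vector<double> mind(n, R_PosInf), minr(n, 0.0);
  for (int e = 0; e < polys.size(); e++) {
    NumericMatrix poly = polys[e];
    NumericVector rad = radii[e];
    for (int s = 0; s + 1 < poly.nrow(); s++) {
      double a[3] = {poly(s, 0), poly(s, 1), poly(s, 2)};
      double b[3] = {poly(s + 1, 0), poly(s + 1, 1), poly(s + 1, 2)};
      double r0 = rad[s], r1 = rad[s + 1];
      double margin = std::max(r0, r1) + 4.0 * width + std::abs(offset);
      int i0 = std::max(0, (int)std::floor((std::min(a[0], b[0]) - margin) / v1));
      int i1 = std::min(d1 - 1, (int)std::ceil((std::max(a[0], b[0]) + margin) / v1));
      int j0 = std::max(0, (int)std::floor((std::min(a[1], b[1]) - margin) / v2));
      int j1 = std::min(d2 - 1, (int)std::ceil((std::max(a[1], b[1]) + margin) / v2));
      int k0 = std::max(0, (int)std::floor((std::min(a[2], b[2]) - margin) / v3));
      int k1 = std::min(d3 - 1, (int)std::ceil((std::max(a[2], b[2]) + margin) / v3));
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++) {
            double p[3] = {(i + 0.5) * v1, (j + 0.5) * v2, (k + 0.5) * v3};
            double t, d = seg_dist(p, a, b, t);
            R_xlen_t q = lin(i, j, k, d1, d2);
            if (d < mind[q]) {
              mind[q] = d;
              minr[q] = r0 + (r1 - r0) * t;
            }
          }
    }
  }
  for (R_xlen_t q = 0; q < n; q++) {
    if (!std::isfinite(mind[q])) continue;
    double dd = mind[q] - (minr[q] - offset);
    double I = amp * std::exp(-dd * dd / (2.0 * width * width));
    if (I > vol[q]) vol[q] = I;
  }
}

// Soma painter: sphere of radius R around `center`, optionally clipped so it
// wraps against a host tube (excluded where centerline distance < clip_r +
// gap). Membrane-weighted label: a soft interior fill at a_in plus a
// Gaussian membrane ridge of sd `rim_w` centered exactly on the soma
// surface (sd = 0), so the fluorescence peak along a radial line sits on
// the surface:
//   I = edge(sd) * a_in + (a_rim - a_in) * exp(-sd^2 / (2 rim_w^2))
// where sd is the signed distance inward from the soma surface.
//' @noRd
// [[Rcpp::export(name = ".paint_soma_cpp")]]
void paint_soma_cpp(NumericVector vol, IntegerVector dim, NumericVector voxel,
                    NumericVector center, double R, double a_in, double a_rim,
                    double rim_w, double edge_w, NumericMatrix clip_poly,
                    NumericVector clip_radii, double clip_gap) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double v1 = voxel[0], v2 = voxel[1], v3 = voxel[2];
  const bool clip = clip_poly.nrow() >= 2;
  double margin = R + 2.0 * edge_w;
  int i0 = std::max(0, (int)std::floor((center[0] - margin) / v1));
  int i1 = std::min(d1 - 1, (int)std::ceil((center[0] + margin) / v1));
  int j0 = std::max(0, (int)std::floor((center[1] - margin) / v2));
  int j1 = std::min(d2 - 1, (int)std::ceil((center[1] + margin) / v2));
  int k0 = std::max(0, (int)std::floor((center[2] - margin) / v3));
  int k1 = std::min(d3 - 1, (int)std::ceil((center[2] + margin) / v3));
  for (int k = k0; k <= k1; k++)
    for (int j = j0; j <= j1; j++)
      for (int i = i0; i <= i1; i++) {
        double p[3] = {(i + 0.5) * v1, (j + 0.5) * v2, (k + 0.5) * v3};
        double dc = std::sqrt((p[0] - center[0]) * (p[0] - center[0]) +
                              (p[1] - center[1]) * (p[1] - center[1]) +
                              (p[2] - center[2]) * (p[2] - center[2]));
        double sd = R - dc;  // distance inward from the spherical surface
        if (clip) {
          double best = R_PosInf;
          for (int s = 0; s + 1 < clip_poly.nrow(); s++) {
            double a[3] = {clip_poly(s, 0), clip_poly(s, 1), clip_poly(s, 2)};
            double b[3] = {clip_poly(s + 1, 0), clip_poly(s + 1, 1),
                           clip_poly(s + 1, 2)};
            double t, d = seg_dist(p, a, b, t);
            double r = clip_radii[s] + (clip_radii[s + 1] - clip_radii[s]) * t;
            best = std::min(best, d - (r + clip_gap));
          }
          sd = std::min(sd, best);  // wrapped cap follows the vessel wall
        }
        if (sd < -3.0 * rim_w && sd < -2.0 * edge_w) continue;
        double edge = clamp01(0.5 + sd / edge_w);
        double I = edge * a_in + (a_rim - a_in) *
          std::exp(-sd * sd / (2.0 * rim_w * rim_w));
        R_xlen_t q = lin(i, j, k, d1, d2);
        if (I > vol[q]) vol[q] = I;
      }
}

//' @noRd
// [[Rcpp::export(name = ".scale_ball_cpp")]]
void scale_ball_cpp(NumericVector vol, IntegerVector dim, NumericVector voxel,
                    NumericVector center, double R, double factor) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double v1 = voxel[0], v2 = voxel[1], v3 = voxel[2];
  int i0 = std::max(0, (int)std::floor((center[0] - R) / v1));
  int i1 = std::min(d1 - 1, (int)std::ceil((center[0] + R) / v1));
  int j0 = std::max(0, (int)std::floor((center[1] - R) / v2));
  int j1 = std::min(d2 - 1, (int)std::ceil((center[1] + R) / v2));
  int k0 = std::max(0, (int)std::floor((center[2] - R) / v3));
  int k1 = std::min(d3 - 1, (int)std::ceil((center[2] + R) / v3));
  for (int k = k0; k <= k1; k++)
    for (int j = j0; j <= j1; j++)
      for (int i = i0; i <= i1; i++) {
        double p[3] = {(i + 0.5) * v1, (j + 0.5) * v2, (k + 0.5) * v3};
        double dc2 = (p[0] - center[0]) * (p[0] - center[0]) +
                     (p[1] - center[1]) * (p[1] - center[1]) +
                     (p[2] - center[2]) * (p[2] - center[2]);
        if (dc2 <= R * R) vol[lin(i, j, k, d1, d2)] *= factor;
      }
}

// separable Gaussian blur, sigma in voxels per axis, reflected boundary
//' @noRd
// [[Rcpp::export(name = ".gauss_blur3_cpp")]]
void gauss_blur3_cpp(NumericVector vol, IntegerVector dim,
                     NumericVector sigma_vox) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * hw + 1);
    double sum = 0;
    for (int t = -hw; t <= hw; t++) {
      ker[t + hw] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + hw];
    }
    for (double& w : ker) w /= sum;
    int n = d[ax];
    std::vector<double> line(n);
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < d[ob]; b++)
      for (int a = 0; a < d[oa]; a++) {
        R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
        for (int t = 0; t < n; t++) line[t] = vol[base + (R_xlen_t)t * stride[ax]];
        for (int t = 0; t < n; t++) {
          double acc = 0;
          for (int u = -hw; u <= hw; u++) {
            int idx = t + u;
            if (idx < 0) idx = -idx - 1;          // reflect
            if (idx >= n) idx = 2 * n - idx - 1;
            if (idx < 0) idx = 0;
            if (idx >= n) idx = n - 1;
            acc += ker[u + hw] * line[idx];
          }
          vol[base + (R_xlen_t)t * stride[ax]] = acc;
        }
      }
  }
}

//' @noRd
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector voxel, NumericMatrix pts) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); p++) {
    double g[3] = {pts(p, 0) / voxel[0] - 0.5, pts(p, 1) / voxel[1] - 0.5,
                   pts(p, 2) / voxel[2] - 0.5};
    int dd[3] = {d1, d2, d3};
    int lo[3];
    double fr[3];
    for (int a = 0; a < 3; a++) {
      double gg = std::min(std::max(g[a], 0.0), (double)dd[a] - 1.0);
      lo[a] = std::min((int)std::floor(gg), dd[a] - 2);
      if (lo[a] < 0) lo[a] = 0;
      fr[a] = gg - lo[a];
      if (dd[a] == 1) { lo[a] = 0; fr[a] = 0; }
    }
    double acc = 0;
    for (int c = 0; c < 8; c++) {
      int ii = lo[0] + (c & 1), jj = lo[1] + ((c >> 1) & 1),
          kk = lo[2] + ((c >> 2) & 1);
      if (ii >= d1) ii = d1 - 1;
      if (jj >= d2) jj = d2 - 1;
      if (kk >= d3) kk = d3 - 1;
      double w = ((c & 1) ? fr[0] : 1 - fr[0]) *
                 (((c >> 1) & 1) ? fr[1] : 1 - fr[1]) *
                 (((c >> 2) & 1) ? fr[2] : 1 - fr[2]);
      acc += w * vol[lin(ii, jj, kk, d1, d2)];
    }
    out[p] = acc;
  }
  return out;
}

// trilinear sampling of one channel of a 4D (a1, a2, a3, channel) array
// without copying the channel out first
//' @noRd
// [[Rcpp::export(name = ".trilinear4_cpp")]]
NumericVector trilinear4_cpp(NumericVector vol, IntegerVector dim4,
                             NumericVector voxel, NumericMatrix pts,
                             int channel) {
  const int d1 = dim4[0], d2 = dim4[1], d3 = dim4[2];
  const R_xlen_t off = (R_xlen_t)(channel - 1) * d1 * d2 * d3;
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); p++) {
    double g[3] = {pts(p, 0) / voxel[0] - 0.5, pts(p, 1) / voxel[1] - 0.5,
                   pts(p, 2) / voxel[2] - 0.5};
    int dd[3] = {d1, d2, d3};
    int lo[3];
    double fr[3];
    for (int a = 0; a < 3; a++) {
      double gg = std::min(std::max(g[a], 0.0), (double)dd[a] - 1.0);
      lo[a] = std::min((int)std::floor(gg), dd[a] - 2);
      if (lo[a] < 0) lo[a] = 0;
      fr[a] = gg - lo[a];
      if (dd[a] == 1) { lo[a] = 0; fr[a] = 0; }
    }
    double acc = 0;
    for (int c = 0; c < 8; c++) {
      int ii = std::min(lo[0] + (c & 1), d1 - 1);
      int jj = std::min(lo[1] + ((c >> 1) & 1), d2 - 1);
      int kk = std::min(lo[2] + ((c >> 2) & 1), d3 - 1);
      double w = ((c & 1) ? fr[0] : 1 - fr[0]) *
                 (((c >> 1) & 1) ? fr[1] : 1 - fr[1]) *
                 (((c >> 2) & 1) ? fr[2] : 1 - fr[2]);
      acc += w * vol[off + lin(ii, jj, kk, d1, d2)];
    }
    out[p] = acc;
  }
  return out;
}

// for each point: distance to the nearest tube surface over all segments of a
// polyline (negative inside the tube), plus nearest-segment info
//' @noRd
// [[Rcpp::export(name = ".tube_surface_dist_cpp")]]
List tube_surface_dist_cpp(NumericMatrix pts, NumericMatrix poly,
                           NumericVector radii) {
  int n = pts.nrow();
  NumericVector dist(n), axdist(n), rad(n);
  IntegerVector seg(n);
  NumericMatrix proj(n, 3);
  for (int p = 0; p < n; p++) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = R_PosInf, bestax = R_PosInf, bestr = NA_REAL;
    int bests = NA_INTEGER;
    double bestproj[3] = {NA_REAL, NA_REAL, NA_REAL};
    for (int s = 0; s + 1 < poly.nrow(); s++) {
      double a[3] = {poly(s, 0), poly(s, 1), poly(s, 2)};
      double b[3] = {poly(s + 1, 0), poly(s + 1, 1), poly(s + 1, 2)};
      double t, d = seg_dist(pp, a, b, t);
      double r = radii[s] + (radii[s + 1] - radii[s]) * t;
      if (d - r < best) {
        best = d - r;
        bestax = d;
        bestr = r;
        bests = s + 1;  // 1-based segment index
        for (int q = 0; q < 3; q++) bestproj[q] = a[q] + t * (b[q] - a[q]);
      }
    }
    dist[p] = best;
    axdist[p] = bestax;
    rad[p] = bestr;
    seg[p] = bests;
    proj(p, 0) = bestproj[0];
    proj(p, 1) = bestproj[1];
    proj(p, 2) = bestproj[2];
  }
  return List::create(_["surface_dist"] = dist, _["axis_dist"] = axdist,
                      _["radius"] = rad, _["segment"] = seg, _["point"] = proj);
}
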