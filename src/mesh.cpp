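#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Marching tetrahedra on a scalar field sampled at voxel centers. Each cube
// between 8 neighboring voxel centers is split into 6 tetrahedra around the
// main diagonal; the isosurface at `level` is triangulated with linear
// interpolation along tetrahedron edges. The result is watertight as long as
// the isosurface does not touch the array boundary (callers pad with a
// below-level frame). Coordinates are micrometres, voxel centers at
// (index - 0.5) * voxel_size + origin.

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// cube corner offsets (a1, a2, a3)
static const int CORN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

struct V3 { double x, y, z; };

static V3 interp(const V3& a, const V3& b, double fa, double fb, double level) {
  double t = (level - fa) / (fb - fa);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  V3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

//' @noRd
// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dim, NumericVector voxel,
                    NumericVector origin, double level) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<double> vx, vy, vz;
  V3 pos[8];
  double val[8];
  for (int k = 0; k + 1 < d3; k++)
    for (int j = 0; j + 1 < d2; j++)
      for (int i = 0; i + 1 < d1; i++) {
        for (int c = 0; c < 8; c++) {
          int ii = i + CORN[c][0], jj = j + CORN[c][1], kk = k + CORN[c][2];
          pos[c].x = origin[0] + (ii + 0.5) * voxel[0];
          pos[c].y = origin[1] + (jj + 0.5) * voxel[1];
          pos[c].z = origin[2] + (kk + 0.5) * voxel[2];
          val[c] = field[(R_xlen_t)ii + (R_xlen_t)jj * d1 +
                         (R_xlen_t)kk * (R_xlen_t)d1 * d2];
        }
        for (int t = 0; t < 6; t++) {
          int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; c++) {
            in[c] = val[id[c]] > level;
            if (in[c]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; c++) {
            if (in[c]) ins[ni++] = id[c]; else outs[no++] = id[c];
          }
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int base[3];
            int nb = 0;
            for (int c = 0; c < 4; c++)
              if (id[c] != apex) base[nb++] = id[c];
            V3 p0 = interp(pos[apex], pos[base[0]], val[apex], val[base[0]], level);
            V3 p1 = interp(pos[apex], pos[base[1]], val[apex], val[base[1]], level);
            V3 p2 = interp(pos[apex], pos[base[2]], val[apex], val[base[2]], level);
            vx.push_back(p0.x); vy.push_back(p0.y); vz.push_back(p0.z);
            vx.push_back(p1.x); vy.push_back(p1.y); vz.push_back(p1.z);
            vx.push_back(p2.x); vy.push_back(p2.y); vz.push_back(p2.z);
          } else {  // 2 in, 2 out: quad split into two triangles
            V3 q00 = interp(pos[ins[0]], pos[outs[0]], val[ins[0]], val[outs[0]], level);
            V3 q01 = interp(pos[ins[0]], pos[outs[1]], val[ins[0]], val[outs[1]], level);
            V3 q10 = interp(pos[ins[1]], pos[outs[0]], val[ins[1]], val[outs[0]], level);
            V3 q11 = interp(pos[ins[1]], pos[outs[1]], val[ins[1]], val[outs[1]], level);
            vx.push_back(q00.x); vy.push_back(q00.y); vz.push_back(q00.z);
            vx.push_back(q01.x); vy.push_back(q01.y); vz.push_back(q01.z);
            vx.push_back(q10.x); vy.push_back(q10.y); vz.push_back(q10.z);
            vx.push_back(q01.x); vy.push_back(q01.y); vz.push_back(q01.z);
            vx.push_back(q11.x); vy.push_back(q11.y); vz.push_back(q11.z);
            vx.push_back(q10.x); vy.push_back(q10.y); vz.push_back(q10.z);
          }
        }
      }
  int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; v++) {
    verts(v, 0) = vx[v];
    verts(v, 1) = vy[v];
    verts(v, 2) = vz[v];
  }
  IntegerMatrix faces(nv / 3, 3);
  for (int f = 0; f < nv / 3; f++) {
    faces(f, 0) = 3 * f + 1;
    faces(f, 1) = 3 * f + 2;
    faces(f, 2) = 3 * f + 3;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
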