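#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// voxel morphology on (d1, d2, d3) logical arrays, R column-major layout

static inline R_xlen_t lin(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)j * d1 + (R_xlen_t)k * (R_xlen_t)d1 * d2;
}

//' @noRd
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int i = (int)(c % d1), j = (int)((c / d1) % d2), k = (int)(c / ((R_xlen_t)d1 * d2));
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (man == 0) continue;
            if (connectivity == 6 && man > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
              continue;
            R_xlen_t n = lin(ii, jj, kk, d1, d2);
            if (mask[n] && !lab[n]) { lab[n] = next; stack.push_back(n); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- TEASAR-style centerline extraction -----------------------------------
//
// Skeletonizes tubular masks by repeatedly tracing Dijkstra shortest paths
// that hug the ridge of the Euclidean distance transform (edge costs carry
// a steep penalty for leaving the medial axis), then "consuming" the tube
// volume around each traced path. New paths start at the farthest
// unconsumed voxel and terminate where they meet the existing skeleton —
// that meeting point is a centerline junction. Deterministic; no iterative
// thinning, so tubes cannot erode from their ends.

struct PQItem {
  double d;
  R_xlen_t s;
  bool operator>(const PQItem& o) const {
    return d > o.d || (d == o.d && s > o.s);
  }
};

//' @noRd
// [[Rcpp::export(name = ".teasar_paths_cpp")]]
List teasar_paths_cpp(LogicalVector mask, NumericVector edt,
                      IntegerVector dim, NumericVector voxel,
                      double consume_scale = 1.2, double ridge_penalty = 10.0) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = mask.size();
  const double maxvox = std::max(voxel[0], std::max(voxel[1], voxel[2]));

  // 26-neighborhood offsets with physical step lengths
  int noffs[26][3];
  double nstep[26];
  int nn = 0;
  for (int dc = -1; dc <= 1; dc++)
    for (int db = -1; db <= 1; db++)
      for (int da = -1; da <= 1; da++) {
        if (!da && !db && !dc) continue;
        noffs[nn][0] = da; noffs[nn][1] = db; noffs[nn][2] = dc;
        nstep[nn] = std::sqrt(da * da * voxel[0] * voxel[0] +
                              db * db * voxel[1] * voxel[1] +
                              dc * dc * voxel[2] * voxel[2]);
        nn++;
      }

  std::vector<int> comp(n, 0);
  std::vector<char> consumed(n, 0), on_skel(n, 0);
  std::vector<int> skel_path(n, -1);       // path id owning a skeleton voxel
  std::vector<double> dist(n);
  std::vector<R_xlen_t> parent(n);

  List out_paths;
  std::vector<int> out_attach_owner;

  int ncomp = 0;
  std::vector<R_xlen_t> cvox;
  for (R_xlen_t seed = 0; seed < n; seed++) {
    if (!mask[seed] || comp[seed]) continue;
    ncomp++;
    // gather component
    cvox.clear();
    {
      std::vector<R_xlen_t> st(1, seed);
      comp[seed] = ncomp;
      while (!st.empty()) {
        R_xlen_t c = st.back(); st.pop_back();
        cvox.push_back(c);
        int i = (int)(c % d1), j = (int)((c / d1) % d2),
            k = (int)(c / ((R_xlen_t)d1 * d2));
        for (int q = 0; q < 26; q++) {
          int ii = i + noffs[q][0], jj = j + noffs[q][1], kk = k + noffs[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            continue;
          R_xlen_t w = lin(ii, jj, kk, d1, d2);
          if (mask[w] && !comp[w]) { comp[w] = ncomp; st.push_back(w); }
        }
      }
    }
    double dmax = 0;
    for (size_t t = 0; t < cvox.size(); t++)
      dmax = std::max(dmax, edt[cvox[t]]);
    if (dmax <= 0) dmax = maxvox;

    // Dijkstra helper over this component
    std::priority_queue<PQItem, std::vector<PQItem>, std::greater<PQItem> > pq;
    const double INF = std::numeric_limits<double>::infinity();
    // find root: farthest voxel (plain geodesic) from the seed
    for (size_t t = 0; t < cvox.size(); t++) dist[cvox[t]] = INF;
    dist[seed] = 0;
    pq.push(PQItem{0, seed});
    R_xlen_t root = seed;
    double best = -1;
    while (!pq.empty()) {
      PQItem it = pq.top(); pq.pop();
      if (it.d > dist[it.s]) continue;
      if (it.d > best) { best = it.d; root = it.s; }
      int i = (int)(it.s % d1), j = (int)((it.s / d1) % d2),
          k = (int)(it.s / ((R_xlen_t)d1 * d2));
      for (int q = 0; q < 26; q++) {
        int ii = i + noffs[q][0], jj = j + noffs[q][1], kk = k + noffs[q][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
          continue;
        R_xlen_t w = lin(ii, jj, kk, d1, d2);
        if (!mask[w]) continue;
        double nd = it.d + nstep[q];
        if (nd < dist[w]) { dist[w] = nd; parent[w] = it.s; pq.push(PQItem{nd, w}); }
      }
    }

    bool first = true;
    int guard = 0;
    while (guard++ < 100000) {
      // multi-source ridge-penalized Dijkstra from the skeleton (or root)
      for (size_t t = 0; t < cvox.size(); t++) dist[cvox[t]] = INF;
      if (first) {
        dist[root] = 0;
        parent[root] = root;
        pq.push(PQItem{0, root});
      } else {
        for (size_t t = 0; t < cvox.size(); t++)
          if (on_skel[cvox[t]]) {
            dist[cvox[t]] = 0;
            parent[cvox[t]] = cvox[t];
            pq.push(PQItem{0, cvox[t]});
          }
      }
      while (!pq.empty()) {
        PQItem it = pq.top(); pq.pop();
        if (it.d > dist[it.s]) continue;
        int i = (int)(it.s % d1), j = (int)((it.s / d1) % d2),
            k = (int)(it.s / ((R_xlen_t)d1 * d2));
        for (int q = 0; q < 26; q++) {
          int ii = i + noffs[q][0], jj = j + noffs[q][1], kk = k + noffs[q][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            continue;
          R_xlen_t w = lin(ii, jj, kk, d1, d2);
          if (!mask[w]) continue;
          // cost per unit length grows with the depth deficit below the
          // ridge, so paths follow the medial axis instead of cutting
          // chords through thick vessels
          double nd = it.d + nstep[q] *
            (1.0 + ridge_penalty / maxvox * (dmax - edt[w]));
          if (nd < dist[w]) { dist[w] = nd; parent[w] = it.s; pq.push(PQItem{nd, w}); }
        }
      }
      // farthest unconsumed voxel
      R_xlen_t target = -1;
      double tb = -1;
      for (size_t t = 0; t < cvox.size(); t++) {
        R_xlen_t s = cvox[t];
        if (consumed[s] || dist[s] == INF) continue;
        if (dist[s] > tb) { tb = dist[s]; target = s; }
      }
      if (target < 0) break;

      // trace back to the skeleton (or root)
      std::vector<R_xlen_t> path;
      R_xlen_t cur = target;
      while (true) {
        path.push_back(cur);
        if (on_skel[cur] || parent[cur] == cur) break;
        cur = parent[cur];
      }
      int attach_owner = -1;
      if (!first && on_skel[path.back()])
        attach_owner = skel_path[path.back()];

      // local ridge estimate along the path (running decayed maximum):
      // near tube ends the raw distance value collapses
      std::vector<double> redt(path.size());
      for (size_t t = 0; t < path.size(); t++) redt[t] = edt[path[t]];
      for (int rep = 0; rep < 4; rep++)
        for (size_t t = 0; t < path.size(); t++) {
          if (t > 0) redt[t] = std::max(redt[t], 0.9 * redt[t - 1]);
          if (t + 1 < path.size()) redt[t] = std::max(redt[t], 0.9 * redt[t + 1]);
        }

      // consume tube volume around the (untrimmed) path
      for (size_t t = 0; t < path.size(); t++) {
        R_xlen_t s = path[t];
        double r = consume_scale * redt[t] + 2.0 * maxvox;
        int i = (int)(s % d1), j = (int)((s / d1) % d2),
            k = (int)(s / ((R_xlen_t)d1 * d2));
        int ri = (int)std::ceil(r / voxel[0]), rj = (int)std::ceil(r / voxel[1]),
            rk = (int)std::ceil(r / voxel[2]);
        for (int kk = std::max(0, k - rk); kk <= std::min(d3 - 1, k + rk); kk++)
          for (int jj = std::max(0, j - rj); jj <= std::min(d2 - 1, j + rj); jj++)
            for (int ii = std::max(0, i - ri); ii <= std::min(d1 - 1, i + ri); ii++) {
              double dx = (ii - i) * voxel[0], dy = (jj - j) * voxel[1],
                     dz = (kk - k) * voxel[2];
              if (dx * dx + dy * dy + dz * dz <= r * r)
                consumed[lin(ii, jj, kk, d1, d2)] = 1;
            }
      }

      // trim low-distance tip flares (the medial axis of a capped tube
      // legitimately ends about one radius before the cap surface)
      size_t t0 = 0, t1 = path.size() - 1;
      while (t0 + 1 < t1 && edt[path[t0]] < 0.6 * redt[t0]) t0++;
      if (first)  // the far end of the trunk is a free tip too
        while (t1 > t0 + 1 && edt[path[t1]] < 0.6 * redt[t1]) t1--;

      if (t1 > t0) {
        int pid = out_paths.size();
        IntegerMatrix pm(t1 - t0 + 1, 3);
        for (size_t t = t0; t <= t1; t++) {
          R_xlen_t s = path[t];
          pm(t - t0, 0) = (int)(s % d1) + 1;      // 1-based for R
          pm(t - t0, 1) = (int)((s / d1) % d2) + 1;
          pm(t - t0, 2) = (int)(s / ((R_xlen_t)d1 * d2)) + 1;
          if (!on_skel[s]) { on_skel[s] = 1; skel_path[s] = pid; }
        }
        out_paths.push_back(pm);
        out_attach_owner.push_back(attach_owner);
      }
      first = false;
    }
  }

  return List::create(_["paths"] = out_paths,
                      _["attach_owner"] = wrap(out_attach_owner));
}
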