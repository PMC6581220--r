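#pragma once
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <algorithm>

// Axis-aligned voxel grid in scanner/head coordinates (mm).
// World position of the corner of voxel (0,0,0) is o; voxel centres sit at
// o + (index + 0.5) * v, with 0-based indices and R column-major flattening.
struct GridP {
  int n[3];
  double v[3], o[3];
  GridP(const Rcpp::IntegerVector &dim, const Rcpp::NumericVector &voxsz,
        const Rcpp::NumericVector &origin) {
    for (int a = 0; a < 3; a++) {
      n[a] = dim[a];
      v[a] = voxsz[a];
      o[a] = origin[a];
    }
  }
  inline int flat(int i, int j, int k) const { return i + n[0] * (j + n[1] * k); }
  inline int nvox() const { return n[0] * n[1] * n[2]; }
};

// Exact incremental ray traversal (Siddon / Amanatides-Woo): visits every
// voxel the segment P1->P2 crosses with its intersection length in mm.
template <typename F>
inline void traverse_ray(const GridP &g, const double *P1, const double *P2, F visit) {
  double d[3] = {P2[0] - P1[0], P2[1] - P1[1], P2[2] - P1[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (!(L > 0.0)) return;

  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; a++) {
    double lo = g.o[a], hi = g.o[a] + g.n[a] * g.v[a];
    if (std::fabs(d[a]) < 1e-12) {
      if (P1[a] < lo || P1[a] >= hi) return;
    } else {
      double ta = (lo - P1[a]) / d[a], tb = (hi - P1[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return;

  const double eps = 1e-10;
  int idx[3], step[3];
  double tmax[3], tdelta[3];
  for (int a = 0; a < 3; a++) {
    double pos = P1[a] + (t0 + eps) * d[a];
    int i = (int)std::floor((pos - g.o[a]) / g.v[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
    if (d[a] > 1e-12) {
      step[a] = 1;
      tmax[a] = (g.o[a] + (i + 1) * g.v[a] - P1[a]) / d[a];
      tdelta[a] = g.v[a] / d[a];
    } else if (d[a] < -1e-12) {
      step[a] = -1;
      tmax[a] = (g.o[a] + i * g.v[a] - P1[a]) / d[a];
      tdelta[a] = -g.v[a] / d[a];
    } else {
      step[a] = 0;
      tmax[a] = std::numeric_limits<double>::infinity();
      tdelta[a] = std::numeric_limits<double>::infinity();
    }
  }

  double tcur = t0;
  while (tcur < t1 - 1e-12) {
    int a = (tmax[0] < tmax[1]) ? (tmax[0] < tmax[2] ? 0 : 2)
                                : (tmax[1] < tmax[2] ? 1 : 2);
    double tnext = std::min(tmax[a], t1);
    double seg = (tnext - tcur) * L;
    if (seg > 0.0) visit(idx[0], idx[1], idx[2], seg);
    tcur = tnext;
    if (tmax[a] >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= g.n[a]) break;
    tmax[a] += tdelta[a];
  }
}
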