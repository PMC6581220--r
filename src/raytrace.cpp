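#include "grid.h"
using namespace Rcpp;

// Single-LOR Siddon trace: 1-based flat voxel indices and chord lengths (mm).
// [[Rcpp::export]]
List cpp_raytrace(NumericVector p1, NumericVector p2, IntegerVector dim,
                  NumericVector voxsz, NumericVector origin) {
  GridP g(dim, voxsz, origin);
  std::vector<int> idx;
  std::vector<double> len;
  double P1[3] = {p1[0], p1[1], p1[2]};
  double P2[3] = {p2[0], p2[1], p2[2]};
  traverse_ray(g, P1, P2, [&](int i, int j, int k, double l) {
    idx.push_back(g.flat(i, j, k) + 1);
    len.push_back(l);
  });
  return List::create(_["index"] = wrap(idx), _["length_mm"] = wrap(len));
}

// Line integrals of a voxelised field along many segments (mm * value units).
// [[Rcpp::export]]
NumericVector cpp_line_integrals(NumericMatrix P1, NumericMatrix P2,
                                 IntegerVector dim, NumericVector voxsz,
                                 NumericVector origin, NumericVector values) {
  GridP g(dim, voxsz, origin);
  int n = P1.nrow();
  NumericVector out(n);
  for (int e = 0; e < n; e++) {
    double a[3] = {P1(e, 0), P1(e, 1), P1(e, 2)};
    double b[3] = {P2(e, 0), P2(e, 1), P2(e, 2)};
    double s = 0.0;
    traverse_ray(g, a, b, [&](int i, int j, int k, double l) {
      s += l * values[g.flat(i, j, k)];
    });
    out[e] = s;
  }
  return out;
}

// Weighted backprojection: for each segment add weight*length into the image.
// Used for the sensitivity image (sum over detector pairs of geometric weight
// times attenuation survival).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix P1, NumericMatrix P2,
                              NumericVector weight, IntegerVector dim,
                              NumericVector voxsz, NumericVector origin) {
  GridP g(dim, voxsz, origin);
  NumericVector img(g.nvox());
  int n = P1.nrow();
  for (int e = 0; e < n; e++) {
    double a[3] = {P1(e, 0), P1(e, 1), P1(e, 2)};
    double b[3] = {P2(e, 0), P2(e, 1), P2(e, 2)};
    double w = weight[e];
    traverse_ray(g, a, b, [&](int i, int j, int k, double l) {
      img[g.flat(i, j, k)] += w * l;
    });
  }
  return img;
}
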