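#include "grid.h"
#include <queue>
using namespace Rcpp;

static inline void dims3(const IntegerVector &dim, int n[3]) {
  n[0] = dim[0]; n[1] = dim[1]; n[2] = dim[2];
}

// Largest 6-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  int n[3];
  dims3(dim, n);
  int nv = n[0] * n[1] * n[2];
  std::vector<int> lab(nv, 0);
  int best_lab = 0, best_size = 0, cur = 0;
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (int start = 0; start < nv; start++) {
    if (!mask[start] || lab[start]) continue;
    cur++;
    int size = 0;
    std::queue<int> q;
    q.push(start);
    lab[start] = cur;
    while (!q.empty()) {
      int p = q.front();
      q.pop();
      size++;
      int i = p % n[0], j = (p / n[0]) % n[1], k = p / (n[0] * n[1]);
      for (int d = 0; d < 6; d++) {
        int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n[0] || jj >= n[1] || kk >= n[2])
          continue;
        int pp = ii + n[0] * (jj + n[1] * kk);
        if (mask[pp] && !lab[pp]) {
          lab[pp] = cur;
          q.push(pp);
        }
      }
    }
    if (size > best_size) {
      best_size = size;
      best_lab = cur;
    }
  }
  LogicalVector out(nv);
  for (int p = 0; p < nv; p++) out[p] = (lab[p] == best_lab) && best_lab > 0;
  return out;
}

// Morphological closing with a 3x3x3 box structuring element.
// [[Rcpp::export]]
LogicalVector cpp_binary_close(LogicalVector mask, IntegerVector dim) {
  int n[3];
  dims3(dim, n);
  int nv = n[0] * n[1] * n[2];
  std::vector<char> a(nv), b(nv);
  for (int p = 0; p < nv; p++) a[p] = mask[p] ? 1 : 0;
  auto pass = [&](std::vector<char> &src, std::vector<char> &dst, bool dilate) {
    for (int k = 0; k < n[2]; k++)
      for (int j = 0; j < n[1]; j++)
        for (int i = 0; i < n[0]; i++) {
          char acc = dilate ? 0 : 1;
          for (int dz = -1; dz <= 1 && (dilate ? !acc : acc); dz++)
            for (int dy = -1; dy <= 1 && (dilate ? !acc : acc); dy++)
              for (int dx = -1; dx <= 1 && (dilate ? !acc : acc); dx++) {
                int ii = i + dx, jj = j + dy, kk = k + dz;
                char val;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= n[0] || jj >= n[1] ||
                    kk >= n[2])
                  // outside is background for dilation but foreground for
                  // erosion, so closing cannot eat the image boundary
                  val = dilate ? 0 : 1;
                else
                  val = src[ii + n[0] * (jj + n[1] * kk)];
                if (dilate && val) acc = 1;
                if (!dilate && !val) acc = 0;
              }
          dst[i + n[0] * (j + n[1] * k)] = acc;
        }
  };
  pass(a, b, true);
  pass(b, a, false);
  LogicalVector out(nv);
  for (int p = 0; p < nv; p++) out[p] = a[p] != 0;
  return out;
}

// Fill interior cavities: background voxels not 6-connected to the grid
// border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int n[3];
  dims3(dim, n);
  int nv = n[0] * n[1] * n[2];
  std::vector<char> outside(nv, 0);
  std::queue<int> q;
  auto push_if = [&](int i, int j, int k) {
    if (i < 0 || j < 0 || k < 0 || i >= n[0] || j >= n[1] || k >= n[2]) return;
    int p = i + n[0] * (j + n[1] * k);
    if (!mask[p] && !outside[p]) {
      outside[p] = 1;
      q.push(p);
    }
  };
  for (int k = 0; k < n[2]; k++)
    for (int j = 0; j < n[1]; j++)
      for (int i = 0; i < n[0]; i++)
        if (i == 0 || j == 0 || k == 0 || i == n[0] - 1 || j == n[1] - 1 ||
            k == n[2] - 1)
          push_if(i, j, k);
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  while (!q.empty()) {
    int p = q.front();
    q.pop();
    int i = p % n[0], j = (p / n[0]) % n[1], k = p / (n[0] * n[1]);
    for (int d = 0; d < 6; d++)
      push_if(i + off[d][0], j + off[d][1], k + off[d][2]);
  }
  LogicalVector out(nv);
  for (int p = 0; p < nv; p++) out[p] = mask[p] || !outside[p];
  return out;
}

// Strict-ish 26-neighbourhood local maxima above an absolute threshold.
// Returns a matrix with 1-based (i, j, k) and the voxel value, brightest
// first.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericVector values, IntegerVector dim,
                               double threshold) {
  int n[3];
  dims3(dim, n);
  std::vector<std::array<double, 4>> hits;
  for (int k = 0; k < n[2]; k++)
    for (int j = 0; j < n[1]; j++)
      for (int i = 0; i < n[0]; i++) {
        double v = values[i + n[0] * (j + n[1] * k)];
        if (!(v > threshold)) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; dz++)
          for (int dy = -1; dy <= 1 && is_max; dy++)
            for (int dx = -1; dx <= 1 && is_max; dx++) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n[0] || jj >= n[1] ||
                  kk >= n[2])
                continue;
              if (values[ii + n[0] * (jj + n[1] * kk)] > v) is_max = false;
            }
        if (is_max) hits.push_back({(double)(i + 1), (double)(j + 1),
                                    (double)(k + 1), v});
      }
  std::sort(hits.begin(), hits.end(),
            [](const std::array<double, 4> &a, const std::array<double, 4> &b) {
              return a[3] > b[3];
            });
  NumericMatrix out(hits.size(), 4);
  for (size_t r = 0; r < hits.size(); r++)
    for (int c = 0; c < 4; c++) out(r, c) = hits[r][c];
  colnames(out) = CharacterVector::create("i", "j", "k", "value");
  return out;
}
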