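#include "grid.h"
using namespace Rcpp;

// Separable Gaussian blur with reflecting boundaries; sigma per axis in
// voxels. Kernel truncated at 3.5 sigma and renormalised.
static void blur_axis(std::vector<double> &img, const GridP &g, int axis,
                      double sigma_vox) {
  if (sigma_vox < 1e-6) return;
  int r = (int)std::ceil(3.5 * sigma_vox);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    ker[i + r] = std::exp(-0.5 * (i * i) / (sigma_vox * sigma_vox));
    s += ker[i + r];
  }
  for (double &k : ker) k /= s;

  int n = g.n[axis];
  int stride = (axis == 0) ? 1 : (axis == 1 ? g.n[0] : g.n[0] * g.n[1]);
  int nline = g.nvox() / n;
  std::vector<double> line(n), out(n);
  for (int l = 0; l < nline; l++) {
    // base offset of this line in the flattened array
    int base;
    if (axis == 0) {
      base = l * n;
    } else if (axis == 1) {
      int i = l % g.n[0], k = l / g.n[0];
      base = i + g.n[0] * g.n[1] * k;
    } else {
      base = l;
    }
    for (int i = 0; i < n; i++) line[i] = img[base + i * stride];
    for (int i = 0; i < n; i++) {
      double acc = 0.0;
      for (int j = -r; j <= r; j++) {
        int p = i + j;
        if (p < 0) p = -p - 1;          // reflect
        if (p >= n) p = 2 * n - p - 1;
        if (p < 0) p = 0;               // very short axes
        if (p >= n) p = n - 1;
        acc += ker[j + r] * line[p];
      }
      out[i] = acc;
    }
    for (int i = 0; i < n; i++) img[base + i * stride] = out[i];
  }
}

static void blur3(std::vector<double> &img, const GridP &g, double sigma_mm) {
  if (sigma_mm <= 0) return;
  for (int a = 0; a < 3; a++) blur_axis(img, g, a, sigma_mm / g.v[a]);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector values, IntegerVector dim,
                             NumericVector voxsz, double sigma_mm) {
  NumericVector origin(3);
  GridP g(dim, voxsz, origin);
  std::vector<double> img(values.begin(), values.end());
  blur3(img, g, sigma_mm);
  return wrap(img);
}

// List-mode OSEM with image-space resolution modelling.
//
// Subsets are formed by event index modulo n_subsets. Per sub-iteration:
//   f_e = sum_j a_ej (x (*) G)_j          (forward projection of blurred image)
//   c_j = sum_{e in subset} a_ej w_e / f_e
//   x_j <- x_j * n_subsets * (c (*) G)_j / S_j   where S_j > 0
// Per-event multiplicative factors (attenuation survival) cancel in the
// ratio, so attenuation enters through the sensitivity image only.
// [[Rcpp::export]]
NumericVector cpp_osem(NumericMatrix P1, NumericMatrix P2, IntegerVector dim,
                       NumericVector voxsz, NumericVector origin,
                       NumericVector sens, int n_subsets, int n_iter,
                       double psf_sigma_mm, Nullable<NumericVector> init_,
                       Nullable<NumericVector> weight_) {
  GridP g(dim, voxsz, origin);
  int nv = g.nvox(), ne = P1.nrow();
  if (ne == 0) stop("empty event set");
  if ((int)sens.size() != nv) stop("sensitivity/grid size mismatch");

  std::vector<double> x(nv), S(sens.begin(), sens.end());
  if (init_.isNotNull()) {
    NumericVector ini(init_);
    if ((int)ini.size() != nv) stop("init/grid size mismatch");
    for (int j = 0; j < nv; j++) x[j] = ini[j];
  } else {
    for (int j = 0; j < nv; j++) x[j] = (S[j] > 0) ? 1.0 : 0.0;
  }
  std::vector<double> w;
  if (weight_.isNotNull()) {
    NumericVector wv(weight_);
    if ((int)wv.size() != ne) stop("weight/event length mismatch");
    w.assign(wv.begin(), wv.end());
  }

  std::vector<int> ibuf;
  std::vector<double> lbuf;
  ibuf.reserve(1024);
  lbuf.reserve(1024);
  std::vector<double> xb(nv), c(nv);
  bool first_pass = true;

  for (int it = 0; it < n_iter; it++) {
    for (int s = 0; s < n_subsets; s++) {
      if (psf_sigma_mm > 0) {
        xb.assign(x.begin(), x.end());
        blur3(xb, g, psf_sigma_mm);
      }
      const std::vector<double> &xf = (psf_sigma_mm > 0) ? xb : x;
      std::fill(c.begin(), c.end(), 0.0);
      for (int e = s; e < ne; e += n_subsets) {
        double a[3] = {P1(e, 0), P1(e, 1), P1(e, 2)};
        double b[3] = {P2(e, 0), P2(e, 1), P2(e, 2)};
        ibuf.clear();
        lbuf.clear();
        double f = 0.0;
        traverse_ray(g, a, b, [&](int i, int j, int k, double l) {
          int id = g.flat(i, j, k);
          ibuf.push_back(id);
          lbuf.push_back(l);
          f += l * xf[id];
        });
        if (!(f > 0.0)) {
          if (first_pass && !ibuf.empty())
            stop("event LOR received zero forward projection: geometry/grid mismatch");
          continue;  // LOR misses the grid, or support vanished later on
        }
        double we = (w.empty() ? 1.0 : w[e]) / f;
        for (size_t q = 0; q < ibuf.size(); q++) c[ibuf[q]] += lbuf[q] * we;
      }
      if (psf_sigma_mm > 0) blur3(c, g, psf_sigma_mm);
      for (int j = 0; j < nv; j++)
        x[j] = (S[j] > 0) ? x[j] * n_subsets * c[j] / S[j] : 0.0;
      first_pass = false;
    }
    Rcpp::checkUserInterrupt();
  }
  return wrap(x);
}

// Trilinear resampling of `values` (living on the input grid) under a rigid
// map: out(x) = in(R x + t), with x the centre of each output voxel; samples
// outside the input grid are 0. Input and output grids may differ.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector values, IntegerVector in_dim,
                                 NumericVector in_voxsz, NumericVector in_origin,
                                 IntegerVector out_dim, NumericVector out_voxsz,
                                 NumericVector out_origin, NumericMatrix R,
                                 NumericVector t) {
  GridP gi(in_dim, in_voxsz, in_origin);
  GridP go(out_dim, out_voxsz, out_origin);
  NumericVector out(go.nvox());
  for (int k = 0; k < go.n[2]; k++)
    for (int j = 0; j < go.n[1]; j++)
      for (int i = 0; i < go.n[0]; i++) {
        double x[3] = {go.o[0] + (i + 0.5) * go.v[0],
                       go.o[1] + (j + 0.5) * go.v[1],
                       go.o[2] + (k + 0.5) * go.v[2]};
        double y[3];
        for (int a = 0; a < 3; a++)
          y[a] = R(a, 0) * x[0] + R(a, 1) * x[1] + R(a, 2) * x[2] + t[a];
        // continuous voxel coordinates of the sample point in the input grid
        double u[3];
        bool ok = true;
        int b[3];
        double fr[3];
        for (int a = 0; a < 3; a++) {
          u[a] = (y[a] - gi.o[a]) / gi.v[a] - 0.5;
          b[a] = (int)std::floor(u[a]);
          fr[a] = u[a] - b[a];
          if (b[a] < -1 || b[a] > gi.n[a] - 1) ok = false;
        }
        if (!ok) continue;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; dz++)
          for (int dy = 0; dy <= 1; dy++)
            for (int dx = 0; dx <= 1; dx++) {
              int ii = b[0] + dx, jj = b[1] + dy, kk = b[2] + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= gi.n[0] ||
                  jj >= gi.n[1] || kk >= gi.n[2])
                continue;
              double wgt = (dx ? fr[0] : 1 - fr[0]) * (dy ? fr[1] : 1 - fr[1]) *
                           (dz ? fr[2] : 1 - fr[2]);
              acc += wgt * values[gi.flat(ii, jj, kk)];
            }
        out[go.flat(i, j, k)] = acc;
      }
  return out;
}
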