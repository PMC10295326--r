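// Numeric kernels: exact Euclidean distance transform, local thickness
// (largest inscribed sphere), dynamic time warping, separable convolution,
// resampling, and im2col/col2im for the translation network.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1-D squared distance transform of a sampled function (Felzenszwalb-
// Huttenlocher lower envelope of parabolas), with physical sample spacing.
static void dt1d(const double* f, double* d, int n, double step,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s = 0.0;
    while (true) {
      int p = v[k];
      double xp = p * step;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * xq - 2.0 * xp);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * step;
    while (z[k + 1] < x) ++k;
    double dx = x - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared EDT of a binary volume: for every voxel, squared distance to the
// nearest zero (background) voxel centre. dim = (n1, n2, n3), first index
// fastest (R array layout); spacing in physical units per axis.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(NumericVector bin, IntegerVector dim,
                       NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  // large finite stand-in for "no background on this line": keeps the
  // parabola-envelope arithmetic free of Inf - Inf
  const double BIG = 1e15;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = bin[i] != 0 ? BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* line = &out[(R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      for (int i = 0; i < n1; ++i) f[i] = line[i];
      dt1d(f.data(), d.data(), n1, spacing[0], v.data(), z.data());
      for (int i = 0; i < n1; ++i) line[i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[i + (R_xlen_t)n1 * n2 * k];
      for (int j = 0; j < n2; ++j) f[j] = base[(R_xlen_t)n1 * j];
      dt1d(f.data(), d.data(), n2, spacing[1], v.data(), z.data());
      for (int j = 0; j < n2; ++j) base[(R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[i + (R_xlen_t)n1 * j];
      for (int k = 0; k < n3; ++k) f[k] = base[s3 * k];
      dt1d(f.data(), d.data(), n3, spacing[2], v.data(), z.data());
      for (int k = 0; k < n3; ++k) base[s3 * k] = d[k];
    }
  return out;
}

// Local thickness (Hildebrand-Ruegsegger): for each foreground voxel the
// diameter (voxel units) of the largest sphere contained in the foreground
// that covers it. Isotropic grids only; caller converts to physical units.
// Sphere radius at centre c is r(c) = dist(c, nearest background centre) - 1/2
// and a voxel v is covered when |v - c| < r(c).
// [[Rcpp::export(name = ".local_thickness_vox")]]
NumericVector local_thickness_vox(NumericVector bin, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector sp(3);
  sp[0] = sp[1] = sp[2] = 1.0;
  NumericVector d2 = edt3d_sq(bin, dim, sp);

  std::vector<double> r(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (bin[i] != 0) r[i] = std::sqrt(d2[i]) - 0.5;

  // Distance ridge: drop centre p when some 26-neighbour q strictly dominates
  // it, i.e. r(q) > r(p) + |p-q| (sphere(p) then lies inside sphere(q)).
  // Ties kept (inclusion), which only adds redundant paint sources.
  const double tol = 1e-9;
  std::vector<char> keep(n, 0);
  R_xlen_t s2 = n1, s3v = (R_xlen_t)n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + s2 * j + s3v * k;
        if (bin[idx] == 0) continue;
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; ++dk)
          for (int dj = -1; dj <= 1 && !dominated; ++dj)
            for (int di = -1; di <= 1 && !dominated; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3)
                continue;
              R_xlen_t q = ii + s2 * jj + s3v * kk;
              if (bin[q] == 0) continue;
              double dist = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[q] - (r[idx] + dist) > tol) dominated = true;
            }
        if (!dominated) keep[idx] = 1;
      }

  // Sphere painting from kept centres.
  NumericVector out(n);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + s2 * j + s3v * k;
        if (!keep[idx]) continue;
        double rc = r[idx];
        double diam = 2.0 * rc;
        int rad = (int)std::floor(rc);
        double rc2 = rc * rc;
        for (int dk = -rad; dk <= rad; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= n3) continue;
          for (int dj = -rad; dj <= rad; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= n2) continue;
            for (int di = -rad; di <= rad; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= n1) continue;
              double dd = (double)(di * di + dj * dj + dk * dk);
              if (dd >= rc2) continue;  // strict |v-c| < r
              R_xlen_t vdx = ii + s2 * jj + s3v * kk;
              if (out[vdx] < diam) out[vdx] = diam;
            }
          }
        }
        if (out[idx] < diam) out[idx] = diam;  // rc < 1 still covers itself
      }
  // every foreground voxel is covered by its own (possibly dominated) sphere
  for (R_xlen_t i = 0; i < n; ++i)
    if (bin[i] != 0 && out[i] < 2.0 * r[i]) out[i] = 2.0 * r[i];
  return out;
}

// ---------------------------------------------------------------------------
// Dynamic time warping over a cost matrix (n x m). Steps {(1,0),(0,1),(1,1)};
// ties in backtracking prefer (1,1), then (0,1), then (1,0).
// Returns list(path = L x 2 matrix of 1-based (i, j), cost = total cost).
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix m) {
  int n = m.nrow(), mm = m.ncol();
  NumericMatrix D(n, mm);
  D(0, 0) = m(0, 0);
  for (int i = 1; i < n; ++i) D(i, 0) = D(i - 1, 0) + m(i, 0);
  for (int j = 1; j < mm; ++j) D(0, j) = D(0, j - 1) + m(0, j);
  for (int i = 1; i < n; ++i)
    for (int j = 1; j < mm; ++j) {
      double best = D(i - 1, j - 1);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      D(i, j) = m(i, j) + best;
    }
  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = mm - 1;
  pi.push_back(i); pj.push_back(j);
  const double eps = 1e-12;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d11 = D(i - 1, j - 1), d01 = D(i, j - 1), d10 = D(i - 1, j);
      double best = std::min(d11, std::min(d01, d10));
      if (d11 <= best + eps) { --i; --j; }
      else if (d01 <= best + eps) { --j; }
      else { --i; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int t = 0; t < L; ++t) {
    path(t, 0) = pi[L - 1 - t] + 1;
    path(t, 1) = pj[L - 1 - t] + 1;
  }
  return List::create(_["path"] = path, _["cost"] = D(n - 1, mm - 1));
}

// ---------------------------------------------------------------------------
// Separable 1-D convolution of a 3-D array along one axis, reflect padding.
// axis is 1, 2 or 3; kernel length must be odd.
// [[Rcpp::export(name = ".convolve_axis")]]
NumericVector convolve_axis(NumericVector x, IntegerVector dim,
                            NumericVector kernel, int axis) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  int klen = kernel.size();
  int half = klen / 2;
  NumericVector out(n);
  int len = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2 ? n1 : (R_xlen_t)n1 * n2);
  std::vector<double> buf(len), res(len);

  R_xlen_t outer1, outer2, so1, so2;
  if (axis == 1) { outer1 = n2; outer2 = n3; so1 = n1; so2 = (R_xlen_t)n1 * n2; }
  else if (axis == 2) { outer1 = n1; outer2 = n3; so1 = 1; so2 = (R_xlen_t)n1 * n2; }
  else { outer1 = n1; outer2 = n2; so1 = 1; so2 = n1; }

  for (R_xlen_t b = 0; b < outer2; ++b)
    for (R_xlen_t a = 0; a < outer1; ++a) {
      R_xlen_t base = a * so1 + b * so2;
      for (int t = 0; t < len; ++t) buf[t] = x[base + stride * t];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -half; u <= half; ++u) {
          int s = t + u;
          if (s < 0) s = -s - 1;            // reflect
          if (s >= len) s = 2 * len - s - 1;
          if (s < 0) s = 0;
          if (s >= len) s = len - 1;
          acc += buf[s] * kernel[u + half];
        }
        res[t] = acc;
      }
      for (int t = 0; t < len; ++t) out[base + stride * t] = res[t];
    }
  return out;
}

// Valid-mode 2-D filtering of a matrix with an arbitrary window.
// [[Rcpp::export(name = ".filter2_valid")]]
NumericMatrix filter2_valid(NumericMatrix img, NumericMatrix w) {
  int h = img.nrow(), wd = img.ncol();
  int kh = w.nrow(), kw = w.ncol();
  int oh = h - kh + 1, ow = wd - kw + 1;
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b)
        for (int a = 0; a < kh; ++a)
          acc += img(i + a, j + b) * w(a, b);
      out(i, j) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a volume. Coordinates are physical: source voxel
// centre t = origin + (i + 1/2) * spacing. Query points given per axis as the
// target grid's centres; outside the source extent values clamp to the edge.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericVector q1, NumericVector q2,
                               NumericVector q3) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int m1 = q1.size(), m2 = q2.size(), m3 = q3.size();
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;

  std::vector<int> i0a(m1), j0a(m2), k0a(m3);
  std::vector<double> fa(m1), fb(m2), fc(m3);
  auto prep = [](NumericVector q, double orig, double sp, int nn,
                 std::vector<int>& idx, std::vector<double>& frac) {
    for (int t = 0; t < (int)idx.size(); ++t) {
      double c = (q[t] - orig) / sp - 0.5;
      if (c < 0) c = 0;
      if (c > nn - 1) c = nn - 1;
      int i0 = (int)std::floor(c);
      if (i0 > nn - 2) i0 = std::max(0, nn - 2);
      idx[t] = i0;
      frac[t] = (nn == 1) ? 0.0 : c - i0;
    }
  };
  prep(q1, origin[0], spacing[0], n1, i0a, fa);
  prep(q2, origin[1], spacing[1], n2, j0a, fb);
  prep(q3, origin[2], spacing[2], n3, k0a, fc);

  R_xlen_t o = 0;
  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i, ++o) {
        int i0 = i0a[i], j0 = j0a[j], k0 = k0a[k];
        double a = fa[i], b = fb[j], c = fc[k];
        int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1),
            k1 = std::min(k0 + 1, n3 - 1);
        double v000 = vol[i0 + s2 * j0 + s3 * k0];
        double v100 = vol[i1 + s2 * j0 + s3 * k0];
        double v010 = vol[i0 + s2 * j1 + s3 * k0];
        double v110 = vol[i1 + s2 * j1 + s3 * k0];
        double v001 = vol[i0 + s2 * j0 + s3 * k1];
        double v101 = vol[i1 + s2 * j0 + s3 * k1];
        double v011 = vol[i0 + s2 * j1 + s3 * k1];
        double v111 = vol[i1 + s2 * j1 + s3 * k1];
        double v00 = v000 * (1 - a) + v100 * a;
        double v10 = v010 * (1 - a) + v110 * a;
        double v01 = v001 * (1 - a) + v101 * a;
        double v11 = v011 * (1 - a) + v111 * a;
        double v0 = v00 * (1 - b) + v10 * b;
        double v1 = v01 * (1 - b) + v11 * b;
        out[o] = v0 * (1 - c) + v1 * c;
      }
  return out;
}

// Catmull-Rom bicubic resize of a matrix to (oh, ow), edge clamped.
// [[Rcpp::export(name = ".bicubic_resize")]]
NumericMatrix bicubic_resize(NumericMatrix img, int oh, int ow) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(oh, ow);
  auto cr = [](double p0, double p1, double p2, double p3, double t) {
    return p1 + 0.5 * t * (p2 - p0 +
           t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
           t * (3.0 * (p1 - p2) + p3 - p0)));
  };
  auto clampi = [](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };
  double sy = (double)h / oh, sx = (double)w / ow;
  for (int j = 0; j < ow; ++j) {
    double xc = (j + 0.5) * sx - 0.5;
    int x1 = (int)std::floor(xc);
    double tx = xc - x1;
    for (int i = 0; i < oh; ++i) {
      double yc = (i + 0.5) * sy - 0.5;
      int y1 = (int)std::floor(yc);
      double ty = yc - y1;
      double col[4];
      for (int b = 0; b < 4; ++b) {
        int xx = clampi(x1 - 1 + b, w);
        double p0 = img(clampi(y1 - 1, h), xx);
        double p1 = img(clampi(y1, h), xx);
        double p2 = img(clampi(y1 + 1, h), xx);
        double p3 = img(clampi(y1 + 2, h), xx);
        col[b] = cr(p0, p1, p2, p3, ty);
      }
      out(i, j) = cr(col[0], col[1], col[2], col[3], tx);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// im2col / col2im for 2-D convolution on (h, w, c) arrays (R layout, first
// index fastest). Zero padding; output rows indexed by (oi + oh*oj), columns
// by (ki + k*kj + k*k*ch) so a weight array dim (k, k, c_in, c_out) flattened
// to (k*k*c_in, c_out) multiplies directly.
// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col(NumericVector x, int h, int w, int c, int k,
                     int stride, int pad) {
  int oh = (h + 2 * pad - k) / stride + 1;
  int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix out((R_xlen_t)oh * ow, (R_xlen_t)k * k * c);
  R_xlen_t sc = (R_xlen_t)h * w;
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t colidx = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * ch;
        for (int oj = 0; oj < ow; ++oj) {
          int j = oj * stride + kj - pad;
          bool jin = (j >= 0 && j < w);
          for (int oi = 0; oi < oh; ++oi) {
            int i = oi * stride + ki - pad;
            double v = 0.0;
            if (jin && i >= 0 && i < h)
              v = x[i + (R_xlen_t)h * j + sc * ch];
            out(oi + (R_xlen_t)oh * oj, colidx) = v;
          }
        }
      }
  return out;
}

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im(NumericMatrix cols, int h, int w, int c, int k,
                     int stride, int pad) {
  int oh = (h + 2 * pad - k) / stride + 1;
  int ow = (w + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)h * w * c);
  R_xlen_t sc = (R_xlen_t)h * w;
  for (int ch = 0; ch < c; ++ch)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t colidx = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * ch;
        for (int oj = 0; oj < ow; ++oj) {
          int j = oj * stride + kj - pad;
          if (j < 0 || j >= w) continue;
          for (int oi = 0; oi < oh; ++oi) {
            int i = oi * stride + ki - pad;
            if (i < 0 || i >= h) continue;
            out[i + (R_xlen_t)h * j + sc * ch] +=
                cols(oi + (R_xlen_t)oh * oj, colidx);
          }
        }
      }
  return out;
}

// Local extrema of a 3-D stack (h, w, L) across 3x3x3 neighbourhoods in the
// interior levels; returns (i, j, level) 1-based for |value| >= thresh.
// [[Rcpp::export(name = ".dog_extrema")]]
IntegerMatrix dog_extrema(NumericVector dog, IntegerVector dim,
                          double thresh, int border) {
  int h = dim[0], w = dim[1], L = dim[2];
  R_xlen_t sl = (R_xlen_t)h * w;
  std::vector<int> ri, rj, rl;
  for (int l = 1; l < L - 1; ++l)
    for (int j = border; j < w - border; ++j)
      for (int i = border; i < h - border; ++i) {
        double v = dog[i + (R_xlen_t)h * j + sl * l];
        if (std::fabs(v) < thresh) continue;
        bool ismax = true, ismin = true;
        for (int dl = -1; dl <= 1 && (ismax || ismin); ++dl)
          for (int dj = -1; dj <= 1 && (ismax || ismin); ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dl == 0) continue;
              double u = dog[(i + di) + (R_xlen_t)h * (j + dj) +
                             sl * (l + dl)];
              if (u >= v) ismax = false;
              if (u <= v) ismin = false;
              if (!ismax && !ismin) break;
            }
        if (ismax || ismin) {
          ri.push_back(i + 1);
          rj.push_back(j + 1);
          rl.push_back(l + 1);
        }
      }
  IntegerMatrix out(ri.size(), 3);
  for (int t = 0; t < (int)ri.size(); ++t) {
    out(t, 0) = ri[t];
    out(t, 1) = rj[t];
    out(t, 2) = rl[t];
  }
  return out;
}
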