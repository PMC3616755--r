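#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Index helper for column-major 3D arrays.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Separable 1D convolution along one axis with reflected (mirror) borders.
static void conv_axis(std::vector<double> &a, int nx, int ny, int nz,
                      const std::vector<double> &ker, int axis) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  int half = ((int)ker.size() - 1) / 2;
  std::vector<double> line(n), out(n);
  int n_outer1 = (axis == 0) ? ny : nx;
  int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; ++o2) {
    for (int o1 = 0; o1 < n_outer1; ++o1) {
      for (int t = 0; t < n; ++t) {
        int i = (axis == 0) ? t : o1;
        int j = (axis == 1) ? t : ((axis == 0) ? o1 : o2);
        int k = (axis == 2) ? t : o2;
        line[t] = a[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < n; ++t) {
        double s = 0.0;
        for (int u = -half; u <= half; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= n) p = 2 * n - p - 1;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          s += line[p] * ker[u + half];
        }
        out[t] = s;
      }
      for (int t = 0; t < n; ++t) {
        int i = (axis == 0) ? t : o1;
        int j = (axis == 1) ? t : ((axis == 0) ? o1 : o2);
        int k = (axis == 2) ? t : o2;
        a[idx3(i, j, k, nx, ny)] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dim, NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int n_ax = dim[axis];
    int half = std::max(1, (int)std::ceil(3.0 * s));
    if (half > n_ax - 1) half = n_ax - 1;   // reflection is only defined there
    std::vector<double> ker(2 * half + 1);
    double tot = 0.0;
    for (int u = -half; u <= half; ++u) {
      ker[u + half] = std::exp(-0.5 * (double)u * (double)u / (s * s));
      tot += ker[u + half];
    }
    for (auto &v : ker) v /= tot;
    conv_axis(a, nx, ny, nz, ker, axis);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), anisotropic step w.
// Background carries a large finite sentinel rather than Inf so envelope
// intersections stay well-defined.
static const double DT_BIG = 1e20;

static void dt1d(std::vector<double> &f, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
    if (d[q] > DT_BIG) d[q] = DT_BIG;
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel; DT_BIG-capped
// (callers treat values >= 1e18 as "no seed").
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 0.0 : DT_BIG;
  std::vector<double> line;
  // axis x
  line.resize(nx);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) line[i] = a[idx3(i, j, k, nx, ny)];
    dt1d(line, nx, spacing[0]);
    for (int i = 0; i < nx; ++i) a[idx3(i, j, k, nx, ny)] = line[i];
  }
  // axis y
  line.resize(ny);
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) line[j] = a[idx3(i, j, k, nx, ny)];
    dt1d(line, ny, spacing[1]);
    for (int j = 0; j < ny; ++j) a[idx3(i, j, k, nx, ny)] = line[j];
  }
  // axis z
  line.resize(nz);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) line[k] = a[idx3(i, j, k, nx, ny)];
    dt1d(line, nz, spacing[2]);
    for (int k = 0; k < nz; ++k) a[idx3(i, j, k, nx, ny)] = line[k];
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling at continuous 0-based voxel coordinates; outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim, NumericMatrix pts,
                            double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 && z <= nz - 1)) {
      out[p] = fill; continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = arr[idx3(i0, j0, k0, nx, ny)];
    double c100 = arr[idx3(i0 + 1, j0, k0, nx, ny)];
    double c010 = arr[idx3(i0, j0 + 1, k0, nx, ny)];
    double c110 = arr[idx3(i0 + 1, j0 + 1, k0, nx, ny)];
    double c001 = arr[idx3(i0, j0, k0 + 1, nx, ny)];
    double c101 = arr[idx3(i0 + 1, j0, k0 + 1, nx, ny)];
    double c011 = arr[idx3(i0, j0 + 1, k0 + 1, nx, ny)];
    double c111 = arr[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector arr, IntegerVector dim, NumericMatrix pts,
                          double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { out[p] = fill; continue; }
    out[p] = arr[idx3(i, j, k, nx, ny)];
  }
  return out;
}

// Voxelize a closed triangle mesh: voxel centers strictly inside -> 1.
// Vertices in continuous 0-based voxel coordinates. Parity count of ray
// crossings along +z at each (x, y) column; rays are offset by a small
// epsilon to dodge edge/vertex hits on watertight meshes.
// [[Rcpp::export]]
LogicalVector cpp_mesh_mask(NumericMatrix verts, IntegerMatrix tris, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double eps = 1e-4;  // ray offset in voxel units
  std::vector<std::vector<double> > cross((size_t)nx * ny);
  int nf = tris.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = tris(f, 0), b = tris(f, 1), c = tris(f, 2);
    double ax = verts(a, 0) - eps, ay = verts(a, 1) - eps, az = verts(a, 2);
    double bx = verts(b, 0) - eps, by = verts(b, 1) - eps, bz = verts(b, 2);
    double cx = verts(c, 0) - eps, cy = verts(c, 1) - eps, cz = verts(c, 2);
    int xlo = std::max(0, (int)std::ceil(std::min(ax, std::min(bx, cx))));
    int xhi = std::min(nx - 1, (int)std::floor(std::max(ax, std::max(bx, cx))));
    int ylo = std::max(0, (int)std::ceil(std::min(ay, std::min(by, cy))));
    int yhi = std::min(ny - 1, (int)std::floor(std::max(ay, std::max(by, cy))));
    for (int yj = ylo; yj <= yhi; ++yj) {
      for (int xi = xlo; xi <= xhi; ++xi) {
        double px = (double)xi, py = (double)yj;
        // 2D barycentric test in the xy-plane
        double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
        if (std::fabs(d) < 1e-14) continue;
        double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        double zc = l1 * az + l2 * bz + l3 * cz;
        cross[(size_t)xi + (size_t)nx * yj].push_back(zc);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int yj = 0; yj < ny; ++yj) {
    for (int xi = 0; xi < nx; ++xi) {
      std::vector<double> &zs = cross[(size_t)xi + (size_t)nx * yj];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // walk the column flipping inside/outside at each crossing
      size_t m = zs.size();
      for (size_t s = 0; s + 1 < m; s += 2) {
        int klo = (int)std::ceil(zs[s]);
        int khi = (int)std::floor(zs[s + 1]);
        if (khi >= nz) khi = nz - 1;
        if (klo < 0) klo = 0;
        for (int k = klo; k <= khi; ++k)
          out[idx3(xi, yj, k, nx, ny)] = true;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Patch NCC block matching. pts: 0-based integer voxel coords (K x 3) in `fixed`.
// Returns K x 5: best integer offset (dx,dy,dz), its NCC, and the best NCC
// among offsets at least 2 voxels away from the winner (ambiguity score; a
// high value flags aperture-ambiguous points such as smooth edges).
// [[Rcpp::export]]
NumericMatrix cpp_ncc_match(NumericVector fixedArr, NumericVector movingArr,
                            IntegerVector dim, IntegerMatrix pts, int hp, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int K = pts.nrow();
  NumericMatrix out(K, 5);
  int pw = 2 * hp + 1;
  int pn = pw * pw * pw;
  int sw = 2 * radius + 1;
  std::vector<double> patch(pn), cand(pn), scores((size_t)sw * sw * sw);
  for (int q = 0; q < K; ++q) {
    int px = pts(q, 0), py = pts(q, 1), pz = pts(q, 2);
    bool ok = (px - hp >= 0 && py - hp >= 0 && pz - hp >= 0 &&
               px + hp < nx && py + hp < ny && pz + hp < nz);
    double best = -2.0, second = -2.0; int bdx = 0, bdy = 0, bdz = 0;
    if (ok) {
      std::fill(scores.begin(), scores.end(), -2.0);
      double fmean = 0.0;
      int t = 0;
      for (int k = -hp; k <= hp; ++k) for (int j = -hp; j <= hp; ++j) for (int i = -hp; i <= hp; ++i) {
        patch[t] = fixedArr[idx3(px + i, py + j, pz + k, nx, ny)];
        fmean += patch[t]; ++t;
      }
      fmean /= pn;
      double fvar = 0.0;
      for (t = 0; t < pn; ++t) { patch[t] -= fmean; fvar += patch[t] * patch[t]; }
      if (fvar > 1e-12) {
        for (int dz = -radius; dz <= radius; ++dz)
        for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx) {
          int cx = px + dx, cy = py + dy, cz = pz + dz;
          if (cx - hp < 0 || cy - hp < 0 || cz - hp < 0 ||
              cx + hp >= nx || cy + hp >= ny || cz + hp >= nz) continue;
          double mmean = 0.0; t = 0;
          for (int k = -hp; k <= hp; ++k) for (int j = -hp; j <= hp; ++j) for (int i = -hp; i <= hp; ++i) {
            cand[t] = movingArr[idx3(cx + i, cy + j, cz + k, nx, ny)];
            mmean += cand[t]; ++t;
          }
          mmean /= pn;
          double mvar = 0.0, cv = 0.0;
          for (t = 0; t < pn; ++t) {
            double d = cand[t] - mmean;
            mvar += d * d; cv += patch[t] * d;
          }
          if (mvar < 1e-12) continue;
          double ncc = cv / std::sqrt(fvar * mvar);
          scores[(size_t)(dx + radius) +
                 (size_t)sw * ((dy + radius) + (size_t)sw * (dz + radius))] = ncc;
          if (ncc > best) { best = ncc; bdx = dx; bdy = dy; bdz = dz; }
        }
        for (int dz = -radius; dz <= radius; ++dz)
        for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx) {
          int ddx = dx - bdx, ddy = dy - bdy, ddz = dz - bdz;
          if (ddx * ddx + ddy * ddy + ddz * ddz < 4) continue;
          double s = scores[(size_t)(dx + radius) +
                            (size_t)sw * ((dy + radius) + (size_t)sw * (dz + radius))];
          if (s > second) second = s;
        }
      }
    }
    out(q, 0) = bdx; out(q, 1) = bdy; out(q, 2) = bdz;
    out(q, 3) = best; out(q, 4) = second;
  }
  return out;
}

// Evaluate a 3D TPS (kernel U(r) = r) at pts (N x 3, mm).
// W: K x 3 nonaffine weights; A: 4 x 3 affine part (row 1 = offset).
// Returns N x 3 displacements.
// [[Rcpp::export]]
NumericMatrix cpp_tps_eval(NumericMatrix pts, NumericMatrix ctrl,
                           NumericMatrix W, NumericMatrix A) {
  R_xlen_t n = pts.nrow();
  int K = ctrl.nrow();
  NumericMatrix out(n, 3);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double vx = A(0, 0) + A(1, 0) * x + A(2, 0) * y + A(3, 0) * z;
    double vy = A(0, 1) + A(1, 1) * x + A(2, 1) * y + A(3, 1) * z;
    double vz = A(0, 2) + A(1, 2) * x + A(2, 2) * y + A(3, 2) * z;
    for (int k = 0; k < K; ++k) {
      double dx = x - ctrl(k, 0), dy = y - ctrl(k, 1), dz = z - ctrl(k, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      vx += W(k, 0) * r; vy += W(k, 1) * r; vz += W(k, 2) * r;
    }
    out(p, 0) = vx; out(p, 1) = vy; out(p, 2) = vz;
  }
  return out;
}
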