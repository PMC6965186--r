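#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Axis order convention: arrays are dim c(nz, ny, nx); linear index
// i = z + nz*(y + ny*x), 0-based. World axes (wx, wy, wz) map to array
// axes (x, y, z); rotation is about the z (first) axis.

static inline double sample_trilinear(const double *v, int nz, int ny, int nx,
                                      double z, double y, double x) {
  // clamp-to-border sampling
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 > nz - 2) z0 = nz - 2 > 0 ? nz - 2 : 0;
  if (y0 > ny - 2) y0 = ny - 2 > 0 ? ny - 2 : 0;
  if (x0 > nx - 2) x0 = nx - 2 > 0 ? nx - 2 : 0;
  int z1 = std::min(z0 + 1, nz - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int x1 = std::min(x0 + 1, nx - 1);
  double fz = z - z0, fy = y - y0, fx = x - x0;
  #define V(a,b,c) v[(a) + (size_t)nz * ((b) + (size_t)ny * (c))]
  double c00 = V(z0,y0,x0) * (1-fz) + V(z1,y0,x0) * fz;
  double c10 = V(z0,y1,x0) * (1-fz) + V(z1,y1,x0) * fz;
  double c01 = V(z0,y0,x1) * (1-fz) + V(z1,y0,x1) * fz;
  double c11 = V(z0,y1,x1) * (1-fz) + V(z1,y1,x1) * fz;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fx) + c1 * fx;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector vol, IntegerVector dim,
                                   NumericVector z, NumericVector y,
                                   NumericVector x) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = z.size();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = sample_trilinear(v, nz, ny, nx, z[i], y[i], x[i]);
  return out;
}

// Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
static inline void keys_weights(double f, double *w) {
  const double a = -0.5;
  double f2 = f * f, f3 = f2 * f;
  w[0] = a * (f3 - 2 * f2 + f);
  w[1] = (a + 2) * f3 - (a + 3) * f2 + 1;
  w[2] = -(a + 2) * f3 + (2 * a + 3) * f2 - a * f;
  w[3] = -a * (f3 - f2);
}

static inline double sample_tricubic(const double *v, int nz, int ny, int nx,
                                     double z, double y, double x) {
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  double wz[4], wy[4], wx[4];
  keys_weights(z - z0, wz);
  keys_weights(y - y0, wy);
  keys_weights(x - x0, wx);
  double acc = 0.0;
  for (int dx = -1; dx <= 2; ++dx) {
    int xi = x0 + dx;
    if (xi < 0) xi = 0; if (xi > nx - 1) xi = nx - 1;
    double accy = 0.0;
    for (int dy = -1; dy <= 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0) yi = 0; if (yi > ny - 1) yi = ny - 1;
      double accz = 0.0;
      for (int dz = -1; dz <= 2; ++dz) {
        int zi = z0 + dz;
        if (zi < 0) zi = 0; if (zi > nz - 1) zi = nz - 1;
        accz += wz[dz + 1] *
          v[(size_t)zi + (size_t)nz * ((size_t)yi + (size_t)ny * xi)];
      }
      accy += wy[dy + 1] * accz;
    }
    acc += wx[dx + 1] * accy;
  }
  return acc;
}

// Pull-back warp: out(x) = vol(x - u(x)), u given per voxel.
// order = 1 (trilinear) or 3 (Keys tricubic).
// [[Rcpp::export]]
NumericVector cpp_warp_volume(NumericVector vol, IntegerVector dim,
                              NumericVector uz, NumericVector uy,
                              NumericVector ux, int order = 3) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dim;
  const double *v = REAL(vol);
  size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i)
        out[i] = order == 1
          ? sample_trilinear(v, nz, ny, nx, z - uz[i], y - uy[i], x - ux[i])
          : sample_tricubic(v, nz, ny, nx, z - uz[i], y - uy[i], x - ux[i]);
  return out;
}

// Cone-beam forward projection, all lengths in voxel units.
// Source at angle th: S = r1*(cos, sin, 0); detector plane at distance r2
// from the source; detector axes e_u = (-sin, cos, 0), e_v = (0, 0, 1).
// Returns array dim c(nv, nu, n_angles) of line integrals (intensity*voxel).
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  double r1, double r2, double pitch,
                                  int nu, int nv, NumericVector angles_rad,
                                  double step) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int na = angles_rad.size();
  NumericVector out((size_t)nv * nu * na);
  out.attr("dim") = IntegerVector::create(nv, nu, na);
  const double *v = REAL(vol);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  // volume AABB in world coords (centered at isocenter)
  double lox = -cx - 0.5, hix = cx + 0.5;
  double loy = -cy - 0.5, hiy = cy + 0.5;
  double loz = -cz - 0.5, hiz = cz + 0.5;
  for (int ia = 0; ia < na; ++ia) {
    double ct = std::cos(angles_rad[ia]), st = std::sin(angles_rad[ia]);
    double sx = r1 * ct, sy = r1 * st, sz = 0.0;
    double d0x = (r1 - r2) * ct, d0y = (r1 - r2) * st;
    for (int iu = 0; iu < nu; ++iu) {
      double du = (iu - cu) * pitch;
      double px_base = d0x - du * st, py_base = d0y + du * ct;
      for (int iv = 0; iv < nv; ++iv) {
        double pz = (iv - cv) * pitch;
        double dx = px_base - sx, dy = py_base - sy, dz = pz - sz;
        double len = std::sqrt(dx*dx + dy*dy + dz*dz);
        dx /= len; dy /= len; dz /= len;
        // slab clip of ray S + t*d against the AABB
        double t0 = 0.0, t1 = len;
        bool miss = false;
        double o[3] = {sx, sy, sz}, d[3] = {dx, dy, dz};
        double lo[3] = {lox, loy, loz}, hi[3] = {hix, hiy, hiz};
        for (int k = 0; k < 3 && !miss; ++k) {
          if (std::fabs(d[k]) < 1e-12) {
            if (o[k] < lo[k] || o[k] > hi[k]) miss = true;
          } else {
            double ta = (lo[k] - o[k]) / d[k], tb = (hi[k] - o[k]) / d[k];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
            if (t0 > t1) miss = true;
          }
        }
        double acc = 0.0;
        if (!miss) {
          int nstep = (int)std::ceil((t1 - t0) / step);
          if (nstep < 1) nstep = 1;
          double h = (t1 - t0) / nstep;
          for (int is = 0; is < nstep; ++is) {
            double t = t0 + (is + 0.5) * h;
            double wx = sx + t * dx, wy = sy + t * dy, wz = sz + t * dz;
            acc += sample_trilinear(v, nz, ny, nx, wz + cz, wy + cy, wx + cx);
          }
          acc *= h;
        }
        out[iv + (size_t)nv * (iu + (size_t)nu * ia)] = acc;
      }
    }
  }
  return out;
}

// FDK backprojection. Projections are ramp-filtered, expressed on the
// isocenter plane with sample spacing `du` (voxel units). `weights` carry
// the per-projection angular-gap factor (delta_beta / 2).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector pdim,
                              NumericVector angles_rad, NumericVector weights,
                              double r1, double du, IntegerVector out_dim) {
  int nv = pdim[0], nu = pdim[1], na = pdim[2];
  int nz = out_dim[0], ny = out_dim[1], nx = out_dim[2];
  NumericVector out((size_t)nz * ny * nx);
  out.attr("dim") = out_dim;
  const double *p = REAL(proj);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
  for (int ia = 0; ia < na; ++ia) {
    double ct = std::cos(angles_rad[ia]), st = std::sin(angles_rad[ia]);
    double w = weights[ia];
    const double *pa = p + (size_t)nv * nu * ia;
    size_t i = 0;
    for (int x = 0; x < nx; ++x) {
      double wx = x - cx;
      for (int y = 0; y < ny; ++y) {
        double wy = y - cy;
        double ell = r1 - (wx * ct + wy * st);
        if (ell < 1e-6) { i += nz; continue; }
        double m = r1 / ell;
        double up = (-wx * st + wy * ct) * m;
        double uu = up / du + cu;
        double w2 = w * m * m;
        for (int z = 0; z < nz; ++z, ++i) {
          double vp = (z - cz) * m;
          double vv = vp / du + cv;
          if (uu < 0 || uu > nu - 1 || vv < 0 || vv > nv - 1) continue;
          int u0 = (int)uu, v0 = (int)vv;
          if (u0 > nu - 2) u0 = nu - 2;
          if (v0 > nv - 2) v0 = nv - 2;
          double fu = uu - u0, fv = vv - v0;
          double a = pa[v0 + (size_t)nv * u0], b = pa[v0 + 1 + (size_t)nv * u0];
          double c = pa[v0 + (size_t)nv * (u0 + 1)],
                 d = pa[v0 + 1 + (size_t)nv * (u0 + 1)];
          double val = (a * (1 - fv) + b * fv) * (1 - fu) +
                       (c * (1 - fv) + d * fv) * fu;
          out[i] += w2 * val;
        }
      }
    }
  }
  return out;
}

// 26-connected flood fill from a seed over a logical array.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill26(LogicalVector fg, IntegerVector dim,
                               IntegerVector seed) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out((size_t)nz * ny * nx);
  out.attr("dim") = dim;
  auto idx = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
  };
  int sz = seed[0], sy = seed[1], sx = seed[2];
  if (sz < 0 || sz >= nz || sy < 0 || sy >= ny || sx < 0 || sx >= nx)
    stop("seed outside volume");
  if (!fg[idx(sz, sy, sx)]) stop("seed voxel is not foreground");
  std::queue<std::array<int,3>> q;
  q.push({sz, sy, sx});
  out[idx(sz, sy, sx)] = TRUE;
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z = c[0] + dz, y = c[1] + dy, x = c[2] + dx;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
            continue;
          size_t j = idx(z, y, x);
          if (fg[j] && !out[j]) { out[j] = TRUE; q.push({z, y, x}); }
        }
  }
  return out;
}

// 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher)
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &vv, std::vector<double> &zz, int n) {
  int k = 0;
  vv[0] = 0; zz[0] = -1e20; zz[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[vv[k]] + vv[k] * vv[k])) / (2.0 * q - 2.0 * vv[k]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k; vv[k] = q; zz[k] = s; zz[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = q - vv[k];
    d[q] = dq * dq + f[vv[k]];
  }
}

// Exact Euclidean distance (in voxels) to the nearest background voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> d2(n);
  const double INF = 1e20;
  for (size_t i = 0; i < n; ++i) d2[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dd(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);
  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nz * (y + (size_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = d2[base + z];
      dt1d(f, dd, vv, zz, nz);
      for (int z = 0; z < nz; ++z) d2[base + z] = dd[z];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d2[z + (size_t)nz * (y + (size_t)ny * x)];
      dt1d(f, dd, vv, zz, ny);
      for (int y = 0; y < ny; ++y) d2[z + (size_t)nz * (y + (size_t)ny * x)] = dd[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d2[z + (size_t)nz * (y + (size_t)ny * x)];
      dt1d(f, dd, vv, zz, nx);
      for (int x = 0; x < nx; ++x) d2[z + (size_t)nz * (y + (size_t)ny * x)] = dd[x];
    }
  NumericVector out(n);
  out.attr("dim") = dim;
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(d2[i]);
  return out;
}

// --- topology-preserving sequential thinning -------------------------------

// Is voxel (z,y,x) simple (removal preserves topology)?  Characterisation of
// Bertrand & Malandain: exactly one 26-connected foreground component in the
// punctured 26-neighbourhood, and exactly one 6-connected background
// component in the 18-neighbourhood that is 6-adjacent to the centre.
static bool is_simple(const std::vector<unsigned char> &img,
                      int nz, int ny, int nx, int z, int y, int x) {
  unsigned char nb[27]; // local 3x3x3, index (dz+1) + 3*(dy+1) + 9*(dx+1)
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        unsigned char v = 0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = img[(size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx)];
        nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = v;
      }
  nb[13] = 0; // puncture centre
  // 26-components of foreground within the 26-neighbourhood
  int labels[27]; for (int i = 0; i < 27; ++i) labels[i] = 0;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    std::vector<int> stack = {i};
    labels[i] = ncomp_fg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            int j = zz + 3 * yy + 9 * xx;
            if (j == 13 || !nb[j] || labels[j]) continue;
            labels[j] = ncomp_fg;
            stack.push_back(j);
          }
    }
  }
  if (ncomp_fg != 1) return false;
  // 6-components of background within N18, 6-adjacent to centre
  auto in_n18 = [](int i) {
    int dz = i % 3 - 1, dy = (i / 3) % 3 - 1, dx = i / 9 - 1;
    int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
    return s >= 1 && s <= 2;
  };
  int blab[27]; for (int i = 0; i < 27; ++i) blab[i] = 0;
  int ncomp_bg = 0;
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  for (int fi = 0; fi < 6; ++fi) {
    int i = face[fi];
    if (nb[i] || blab[i]) continue;
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    std::vector<int> stack = {i};
    blab[i] = ncomp_bg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int zz = cz + d6[k][0], yy = cy + d6[k][1], xx = cx + d6[k][2];
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int j = zz + 3 * yy + 9 * xx;
        if (j == 13 || nb[j] || blab[j] || !in_n18(j)) continue;
        blab[j] = ncomp_bg;
        stack.push_back(j);
      }
    }
  }
  return ncomp_bg == 1;
}

static int count_nb26(const std::vector<unsigned char> &img,
                      int nz, int ny, int nx, int z, int y, int x) {
  int c = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dz && !dy && !dx) continue;
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        c += img[(size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx)];
      }
  return c;
}

// Sequential thinning to a unit-width curve skeleton: foreground voxels are
// visited in increasing distance-transform order and removed when simple,
// on the border, and not a curve endpoint; repeated until stable.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<unsigned char> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  NumericVector dist = cpp_edt(mask, dim);
  std::vector<size_t> fg;
  fg.reserve(n / 8);
  for (size_t i = 0; i < n; ++i) if (img[i]) fg.push_back(i);
  std::sort(fg.begin(), fg.end(), [&](size_t a, size_t b) {
    return dist[a] < dist[b];
  });
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t k = 0; k < fg.size(); ++k) {
      size_t i = fg[k];
      if (!img[i]) continue;
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((size_t)nz * ny));
      int nnb = count_nb26(img, nz, ny, nx, z, y, x);
      if (nnb <= 1) continue;                    // endpoint or isolated
      if (!is_simple(img, nz, ny, nx, z, y, x)) continue;
      img[i] = 0;
      changed = true;
    }
  }
  LogicalVector out(n);
  out.attr("dim") = dim;
  for (size_t i = 0; i < n; ++i) out[i] = img[i] ? TRUE : FALSE;
  return out;
}
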