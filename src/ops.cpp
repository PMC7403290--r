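// Numerical kernels: 3D valid convolution (forward/backward), average
// pooling, nearest-neighbour upsampling, trilinear/nearest grid resampling,
// in-plane warp for augmentation, connected-component labelling, and channel
// argmax. Arrays are R column-major with axis order (x, y, z[, c]).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector b, bool relu) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  if (wd[3] != Ci) stop("weight input channels do not match input");
  const int OX = X - kx + 1, OY = Y - ky + 1, OZ = Z - kz + 1;
  if (OX < 1 || OY < 1 || OZ < 1) stop("input smaller than kernel");
  const size_t on = (size_t)OX * OY * OZ;
  NumericVector out((R_xlen_t)(on * Co));
  const double *xp = REAL(x), *wp = REAL(w);
  double *op = REAL(out);

  for (int co = 0; co < Co; ++co) {
    double bb = b[co];
    double *o = op + on * co;
    for (size_t t = 0; t < on; ++t) o[t] = bb;
  }
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dz = 0; dz < kz; ++dz)
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx) {
            const double wv =
              wp[dx + (size_t)kx * (dy + (size_t)ky * (dz + (size_t)kz * (ci + (size_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int z = 0; z < OZ; ++z)
              for (int y = 0; y < OY; ++y) {
                const double *xr =
                  xp + dx + (size_t)X * ((y + dy) + (size_t)Y * ((z + dz) + (size_t)Z * ci));
                double *orow = op + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * co));
                for (int i = 0; i < OX; ++i) orow[i] += wv * xr[i];
              }
          }
  if (relu) {
    const size_t n = (size_t)out.size();
    for (size_t t = 0; t < n; ++t) if (op[t] < 0.0) op[t] = 0.0;
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Co);
  return out;
}

// g must already be masked by the activation derivative (ReLU) in the caller.
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector g) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int OX = X - kx + 1, OY = Y - ky + 1, OZ = Z - kz + 1;
  const size_t on = (size_t)OX * OY * OZ;
  NumericVector gx((R_xlen_t)((size_t)X * Y * Z * Ci));
  NumericVector gw((R_xlen_t)w.size());
  NumericVector gb(Co);
  const double *xp = REAL(x), *wp = REAL(w), *gp = REAL(g);
  double *gxp = REAL(gx), *gwp = REAL(gw);

  for (int co = 0; co < Co; ++co) {
    const double *gc = gp + on * co;
    double acc = 0.0;
    for (size_t t = 0; t < on; ++t) acc += gc[t];
    gb[co] = acc;
  }
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dz = 0; dz < kz; ++dz)
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx) {
            const size_t wi =
              dx + (size_t)kx * (dy + (size_t)ky * (dz + (size_t)kz * (ci + (size_t)Ci * co)));
            const double wv = wp[wi];
            double gwacc = 0.0;
            for (int z = 0; z < OZ; ++z)
              for (int y = 0; y < OY; ++y) {
                const size_t xoff =
                  dx + (size_t)X * ((y + dy) + (size_t)Y * ((z + dz) + (size_t)Z * ci));
                const double *xr = xp + xoff;
                double *gxr = gxp + xoff;
                const double *grow = gp + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * co));
                for (int i = 0; i < OX; ++i) {
                  gxr[i] += wv * grow[i];
                  gwacc += xr[i] * grow[i];
                }
              }
            gwp[wi] = gwacc;
          }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Average pooling with floor division: trailing voxels that do not fill a
// complete block are dropped.
// [[Rcpp::export]]
NumericVector cpp_pool_avg_fw(NumericVector x, IntegerVector xd, IntegerVector k) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int OX = X / kx, OY = Y / ky, OZ = Z / kz;
  if (OX < 1 || OY < 1 || OZ < 1) stop("input smaller than pooling window");
  NumericVector out((R_xlen_t)((size_t)OX * OY * OZ * C));
  const double *xp = REAL(x);
  double *op = REAL(out);
  const double inv = 1.0 / ((double)kx * ky * kz);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int i = 0; i < OX; ++i) {
          double acc = 0.0;
          for (int dz = 0; dz < kz; ++dz)
            for (int dy = 0; dy < ky; ++dy)
              for (int dx = 0; dx < kx; ++dx)
                acc += xp[(i * kx + dx) +
                          (size_t)X * ((y * ky + dy) + (size_t)Y * ((z * kz + dz) + (size_t)Z * c))];
          op[i + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * c))] = acc * inv;
        }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pool_avg_bw(NumericVector g, IntegerVector xd, IntegerVector k) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int OX = X / kx, OY = Y / ky, OZ = Z / kz;
  NumericVector gx((R_xlen_t)((size_t)X * Y * Z * C));
  const double *gp = REAL(g);
  double *gxp = REAL(gx);
  const double inv = 1.0 / ((double)kx * ky * kz);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int i = 0; i < OX; ++i) {
          const double gv = gp[i + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * c))] * inv;
          for (int dz = 0; dz < kz; ++dz)
            for (int dy = 0; dy < ky; ++dy)
              for (int dx = 0; dx < kx; ++dx)
                gxp[(i * kx + dx) +
                    (size_t)X * ((y * ky + dy) + (size_t)Y * ((z * kz + dz) + (size_t)Z * c))] = gv;
        }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, IntegerVector xd, IntegerVector k) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int OX = X * kx, OY = Y * ky, OZ = Z * kz;
  NumericVector out((R_xlen_t)((size_t)OX * OY * OZ * C));
  const double *xp = REAL(x);
  double *op = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int i = 0; i < OX; ++i)
          op[i + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * c))] =
            xp[(i / kx) + (size_t)X * ((y / ky) + (size_t)Y * ((z / kz) + (size_t)Z * c))];
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector g, IntegerVector xd, IntegerVector k) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = k[0], ky = k[1], kz = k[2];
  const int OX = X * kx, OY = Y * ky, OZ = Z * kz;
  NumericVector gx((R_xlen_t)((size_t)X * Y * Z * C));
  const double *gp = REAL(g);
  double *gxp = REAL(gx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int i = 0; i < OX; ++i)
          gxp[(i / kx) + (size_t)X * ((y / ky) + (size_t)Y * ((z / kz) + (size_t)Z * c))] +=
            gp[i + (size_t)OX * (y + (size_t)OY * (z + (size_t)OZ * c))];
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample a 3D scalar field onto a destination grid. World position of
// voxel i is origin + i * spacing (0-based voxel-centre convention).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sd,
                           NumericVector sspac, NumericVector sorig,
                           IntegerVector dd, NumericVector dspac,
                           NumericVector dorig, bool nearest) {
  const int SX = sd[0], SY = sd[1], SZ = sd[2];
  const int DX = dd[0], DY = dd[1], DZ = dd[2];
  NumericVector out((R_xlen_t)((size_t)DX * DY * DZ));
  const double *sp = REAL(src);
  double *op = REAL(out);
  for (int z = 0; z < DZ; ++z)
    for (int y = 0; y < DY; ++y)
      for (int i = 0; i < DX; ++i) {
        const double ux = clampd((dorig[0] + i * dspac[0] - sorig[0]) / sspac[0], 0.0, SX - 1.0);
        const double uy = clampd((dorig[1] + y * dspac[1] - sorig[1]) / sspac[1], 0.0, SY - 1.0);
        const double uz = clampd((dorig[2] + z * dspac[2] - sorig[2]) / sspac[2], 0.0, SZ - 1.0);
        double v;
        if (nearest) {
          const int nx = (int)std::lround(ux), ny = (int)std::lround(uy), nz = (int)std::lround(uz);
          v = sp[nx + (size_t)SX * (ny + (size_t)SY * nz)];
        } else {
          const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy), z0 = (int)std::floor(uz);
          const int x1 = x0 + 1 < SX ? x0 + 1 : x0;
          const int y1 = y0 + 1 < SY ? y0 + 1 : y0;
          const int z1 = z0 + 1 < SZ ? z0 + 1 : z0;
          const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
          double c00 = sp[x0 + (size_t)SX * (y0 + (size_t)SY * z0)] * (1 - fx) +
                       sp[x1 + (size_t)SX * (y0 + (size_t)SY * z0)] * fx;
          double c10 = sp[x0 + (size_t)SX * (y1 + (size_t)SY * z0)] * (1 - fx) +
                       sp[x1 + (size_t)SX * (y1 + (size_t)SY * z0)] * fx;
          double c01 = sp[x0 + (size_t)SX * (y0 + (size_t)SY * z1)] * (1 - fx) +
                       sp[x1 + (size_t)SX * (y0 + (size_t)SY * z1)] * fx;
          double c11 = sp[x0 + (size_t)SX * (y1 + (size_t)SY * z1)] * (1 - fx) +
                       sp[x1 + (size_t)SX * (y1 + (size_t)SY * z1)] * fx;
          const double e0 = c00 * (1 - fy) + c10 * fy;
          const double e1 = c01 * (1 - fy) + c11 * fy;
          v = e0 * (1 - fz) + e1 * fz;
        }
        op[i + (size_t)DX * (y + (size_t)DY * z)] = v;
      }
  out.attr("dim") = IntegerVector::create(DX, DY, DZ);
  return out;
}

// In-plane (x, y) rotation plus isotropic scaling about the array centre,
// sampled by inverse mapping with edge clamping. Used for patch augmentation.
// [[Rcpp::export]]
NumericVector cpp_warp_inplane(NumericVector src, IntegerVector sd,
                               double angle, double scale, bool nearest) {
  const int X = sd[0], Y = sd[1], Z = sd[2];
  NumericVector out((R_xlen_t)((size_t)X * Y * Z));
  const double *sp = REAL(src);
  double *op = REAL(out);
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0, cz = (Z - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  for (int z = 0; z < Z; ++z) {
    const double uz = clampd(cz + (z - cz) / scale, 0.0, Z - 1.0);
    for (int y = 0; y < Y; ++y)
      for (int i = 0; i < X; ++i) {
        const double rx = (i - cx) / scale, ry = (y - cy) / scale;
        const double ux = clampd(cx + ca * rx + sa * ry, 0.0, X - 1.0);
        const double uy = clampd(cy - sa * rx + ca * ry, 0.0, Y - 1.0);
        double v;
        if (nearest) {
          v = sp[(int)std::lround(ux) +
                 (size_t)X * ((int)std::lround(uy) + (size_t)Y * (int)std::lround(uz))];
        } else {
          const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy), z0 = (int)std::floor(uz);
          const int x1 = x0 + 1 < X ? x0 + 1 : x0;
          const int y1 = y0 + 1 < Y ? y0 + 1 : y0;
          const int z1 = z0 + 1 < Z ? z0 + 1 : z0;
          const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
          const double c00 = sp[x0 + (size_t)X * (y0 + (size_t)Y * z0)] * (1 - fx) +
                             sp[x1 + (size_t)X * (y0 + (size_t)Y * z0)] * fx;
          const double c10 = sp[x0 + (size_t)X * (y1 + (size_t)Y * z0)] * (1 - fx) +
                             sp[x1 + (size_t)X * (y1 + (size_t)Y * z0)] * fx;
          const double c01 = sp[x0 + (size_t)X * (y0 + (size_t)Y * z1)] * (1 - fx) +
                             sp[x1 + (size_t)X * (y0 + (size_t)Y * z1)] * fx;
          const double c11 = sp[x0 + (size_t)X * (y1 + (size_t)Y * z1)] * (1 - fx) +
                             sp[x1 + (size_t)X * (y1 + (size_t)Y * z1)] * fx;
          const double e0 = c00 * (1 - fy) + c10 * fy;
          const double e1 = c01 * (1 - fy) + c11 * fy;
          v = e0 * (1 - fz) + e1 * fz;
        }
        op[i + (size_t)X * (y + (size_t)Y * z)] = v;
      }
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}

// Connected-component labelling of a binary mask under 6- or 26-connectivity.
// Components are numbered 1..K in order of their first voxel in linear scan
// order (x fastest, z slowest), i.e. by lowest (z, y, x).
// [[Rcpp::export]]
IntegerVector cpp_cc3d(IntegerVector mask, IntegerVector d, int connectivity) {
  const int X = d[0], Y = d[1], Z = d[2];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector lab((R_xlen_t)n);
  const int *mp = INTEGER(mask);
  int *lp = INTEGER(lab);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mp[s] || lp[s]) continue;
    ++next;
    lp[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int cx = (int)(cur % X);
      const int cy = (int)((cur / X) % Y);
      const int cz = (int)(cur / ((size_t)X * Y));
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int nx = cx + offs[o], ny = cy + offs[o + 1], nz = cz + offs[o + 2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
        const size_t ni = nx + (size_t)X * (ny + (size_t)Y * nz);
        if (mp[ni] && !lp[ni]) { lp[ni] = next; stack.push_back(ni); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(X, Y, Z);
  lab.attr("n_components") = next;
  return lab;
}

// Channel argmax over a (X, Y, Z, C) array; ties broken toward the lower
// channel index. Returns 1-based channel indices.
// [[Rcpp::export]]
IntegerVector cpp_argmax4(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const size_t n = (size_t)X * Y * Z;
  IntegerVector out((R_xlen_t)n);
  const double *xp = REAL(x);
  int *op = INTEGER(out);
  for (size_t t = 0; t < n; ++t) {
    int best = 0;
    double bv = xp[t];
    for (int c = 1; c < C; ++c) {
      const double v = xp[t + n * c];
      if (v > bv) { bv = v; best = c; }
    }
    op[t] = best + 1;
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}
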