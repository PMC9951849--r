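// Low-level numerical kernels: trilinear sampling/warping (with analytic
// gradients for training), im2col-based 2D/3D convolution, max pooling,
// trilinear resizing and its adjoint, ray-cast projection, and separable
// Gaussian smoothing. All arrays are column-major R arrays; spatial axes
// first, channel axis last. Voxel coordinates are 0-based here.
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void axpy(int n, double a, const double* x, double* y) {
  int one = 1;
  F77_CALL(daxpy)(&n, &a, x, &one, y, &one);
}
static inline double dot(int n, const double* x, const double* y) {
  int one = 1;
  return F77_CALL(ddot)(&n, x, &one, y, &one);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample with edge clamping (out-of-range coordinates take the
// boundary value).
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) { x0 = 0; fx = 0.0; }
  if (ny == 1) { y0 = 0; fy = 0.0; }
  if (nz == 1) { z0 = 0; fz = 0.0; }
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  #define V(i,j,k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
  double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
  double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
  double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
  #undef V
}

// Value and spatial gradient (d value / d coordinate) of the clamped
// trilinear interpolant. The gradient is the one-sided derivative of the
// piecewise-linear interpolant; it is zero in clamped directions.
static inline void tri_sample_grad(const double* v, int nx, int ny, int nz,
                                   double x, double y, double z,
                                   double* val, double* gx, double* gy, double* gz) {
  bool cx = (x <= 0.0 || x >= nx - 1.0);
  bool cy = (y <= 0.0 || y >= ny - 1.0);
  bool cz = (z <= 0.0 || z >= nz - 1.0);
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (nx == 1) { x0 = 0; fx = 0.0; cx = true; }
  if (ny == 1) { y0 = 0; fy = 0.0; cy = true; }
  if (nz == 1) { z0 = 0; fz = 0.0; cz = true; }
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  #define V(i,j,k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double v000 = V(x0,y0,z0), v100 = V(x1,y0,z0), v010 = V(x0,y1,z0), v110 = V(x1,y1,z0);
  double v001 = V(x0,y0,z1), v101 = V(x1,y0,z1), v011 = V(x0,y1,z1), v111 = V(x1,y1,z1);
  #undef V
  double c00 = v000*(1-fx) + v100*fx, c10 = v010*(1-fx) + v110*fx;
  double c01 = v001*(1-fx) + v101*fx, c11 = v011*(1-fx) + v111*fx;
  double c0 = c00*(1-fy) + c10*fy, c1 = c01*(1-fy) + c11*fy;
  *val = c0*(1-fz) + c1*fz;
  // d/dx
  double d00 = v100 - v000, d10 = v110 - v010, d01 = v101 - v001, d11 = v111 - v011;
  double dx = (d00*(1-fy) + d10*fy)*(1-fz) + (d01*(1-fy) + d11*fy)*fz;
  // d/dy
  double e0 = c10 - c00, e1 = c11 - c01;
  double dy = e0*(1-fz) + e1*fz;
  // d/dz
  double dz = c1 - c0;
  *gx = cx ? 0.0 : dx;
  *gy = cy ? 0.0 : dy;
  *gz = cz ? 0.0 : dz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, NumericMatrix pts) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = tri_sample(v, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2));
  return out;
}

// Backward warp: out(x) = vol(x + field(x)), field in voxel units,
// dims(field) = c(nx,ny,nz,3). mode 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector field, int mode) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = d;
  const double* v = vol.begin();
  const double* f = field.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + f[idx];
        double y = j + f[idx + nvox];
        double z = k + f[idx + 2*nvox];
        if (mode == 1) {
          int xi = clampi((int)std::lround(x), 0, nx - 1);
          int yi = clampi((int)std::lround(y), 0, ny - 1);
          int zi = clampi((int)std::lround(z), 0, nz - 1);
          out[idx] = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          out[idx] = tri_sample(v, nx, ny, nz, x, y, z);
        }
      }
  return out;
}

// Gradient of sum(gout * warp(vol, field)) with respect to the field
// (voxel units). Returns an array shaped like the field.
// [[Rcpp::export]]
NumericVector cpp_warp_field_grad(NumericVector vol, NumericVector field,
                                  NumericVector gout) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector gf(3 * nvox);
  gf.attr("dim") = field.attr("dim");
  const double* v = vol.begin();
  const double* f = field.begin();
  const double* g = gout.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double val, gx, gy, gz;
        tri_sample_grad(v, nx, ny, nz, i + f[idx], j + f[idx + nvox],
                        k + f[idx + 2*nvox], &val, &gx, &gy, &gz);
        gf[idx]          = g[idx] * gx;
        gf[idx + nvox]   = g[idx] * gy;
        gf[idx + 2*nvox] = g[idx] * gz;
      }
  return gf;
}

// ---------------------------------------------------------------------------
// Ray-cast projection. The volume occupies the physical box
// [-0.5*sp, (n-0.5)*sp] per axis (voxel centres at idx*sp); samples inside
// the box use clamped trilinear interpolation, samples outside contribute 0.
// Detector axes: u = (cos t, -sin t, 0), v = (0, 0, 1); ray direction
// (sin t, cos t, 0), t = angle in radians about the z (SI) axis.
// parallel beam: all rays share the direction; cone beam: rays emanate from
// a source at distance sad upstream of the volume centre.
// [[Rcpp::export]]
NumericMatrix cpp_raycast(NumericVector vol, NumericVector spacing,
                          double angle_deg, IntegerVector det_n,
                          NumericVector det_spacing, double step_mm,
                          bool parallel, double sad) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* v = vol.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double cx = 0.5 * (nx - 1) * sx, cy = 0.5 * (ny - 1) * sy,
         cz = 0.5 * (nz - 1) * sz;
  double lox = -0.5 * sx, hix = (nx - 0.5) * sx;
  double loy = -0.5 * sy, hiy = (ny - 0.5) * sy;
  double loz = -0.5 * sz, hiz = (nz - 0.5) * sz;
  double t = angle_deg * M_PI / 180.0;
  double dirx = std::sin(t), diry = std::cos(t);
  double ux = std::cos(t), uy = -std::sin(t);
  int nu = det_n[0], nv = det_n[1];
  double du = det_spacing[0], dv = det_spacing[1];
  // half-length of the march: cover the volume diagonal
  double half = 0.5 * std::sqrt((hix-lox)*(hix-lox) + (hiy-loy)*(hiy-loy) +
                                (hiz-loz)*(hiz-loz)) + step_mm;
  NumericMatrix out(nu, nv);
  for (int jv = 0; jv < nv; ++jv) {
    double voff = (jv - 0.5 * (nv - 1)) * dv;
    for (int iu = 0; iu < nu; ++iu) {
      double uoff = (iu - 0.5 * (nu - 1)) * du;
      // detector pixel position (on the plane through the volume centre)
      double px = cx + uoff * ux, py = cy + uoff * uy, pz = cz + voff;
      double rx, ry, rz, ox, oy, oz, tmax;
      if (parallel) {
        rx = dirx; ry = diry; rz = 0.0;
        ox = px - half * rx; oy = py - half * ry; oz = pz;
        tmax = 2.0 * half;
      } else {
        double sxp = cx - sad * dirx, syp = cy - sad * diry, szp = cz;
        rx = px - sxp; ry = py - syp; rz = pz - szp;
        double nrm = std::sqrt(rx*rx + ry*ry + rz*rz);
        rx /= nrm; ry /= nrm; rz /= nrm;
        double t0 = std::max(0.0, sad - half);
        ox = sxp + t0 * rx; oy = syp + t0 * ry; oz = szp + t0 * rz;
        tmax = sad + half - t0;
      }
      double acc = 0.0;
      int nstep = (int)std::ceil(tmax / step_mm);
      for (int s = 0; s < nstep; ++s) {
        double tt = (s + 0.5) * step_mm;
        double X = ox + tt * rx, Y = oy + tt * ry, Z = oz + tt * rz;
        if (X < lox || X > hix || Y < loy || Y > hiy || Z < loz || Z > hiz)
          continue;
        acc += tri_sample(v, nx, ny, nz, X / sx, Y / sy, Z / sz);
      }
      out(iu, jv) = acc * step_mm;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D convolution, kernel k x k x k (k odd), padding (k-1)/2, given stride.
// x: [nx,ny,nz,cin]; W: [cout, cin*k^3]; b: [cout]. W's second axis is
// ordered channel-major, then kz, ky, kx. Internally the patch matrix is
// held transposed ([ncol x K], one contiguous column per kernel tap) so
// the stride-1 path reduces to line-run copies and the output/gradient
// matrices coincide with R's [space, channel] memory order.
static arma::mat build_colsT3d(const double* x, int nx, int ny, int nz,
                               int cin, int k, int stride,
                               int ox, int oy, int oz) {
  int pad = (k - 1) / 2;
  size_t nvox_in = (size_t)nx * ny * nz;
  size_t ncol = (size_t)ox * oy * oz;
  size_t K = (size_t)cin * k * k * k;
  arma::mat colsT(ncol, K);
  size_t r = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + ci * nvox_in;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          double* dst = colsT.colptr(r);
          int xoff = kx - pad;
          for (int zo = 0; zo < oz; ++zo) {
            int z = zo * stride + kz - pad;
            for (int yo = 0; yo < oy; ++yo) {
              int y = yo * stride + ky - pad;
              double* line = dst + (size_t)ox * (yo + (size_t)oy * zo);
              if (y < 0 || y >= ny || z < 0 || z >= nz) {
                std::fill(line, line + ox, 0.0);
                continue;
              }
              const double* src = xc + (size_t)nx * (y + (size_t)ny * z);
              if (stride == 1) {
                int lo = std::max(0, -xoff);
                int hi = std::min(ox, nx - xoff);
                if (lo > 0) std::fill(line, line + lo, 0.0);
                if (hi > lo) std::copy(src + lo + xoff, src + hi + xoff, line + lo);
                if (hi < ox) std::fill(line + std::max(hi, 0), line + ox, 0.0);
              } else {
                for (int xo = 0; xo < ox; ++xo) {
                  int xx = xo * stride + xoff;
                  line[xo] = (xx < 0 || xx >= nx) ? 0.0 : src[xx];
                }
              }
            }
          }
        }
  }
  return colsT;
}

// zero-padded copy of one channel (pad voxels on every side)
static void pad_channel3d(const double* src, int nx, int ny, int nz, int pad,
                          double* dst) {
  int px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  std::fill(dst, dst + (size_t)px * py * pz, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const double* s = src + (size_t)nx * (y + (size_t)ny * z);
      double* t = dst + pad + (size_t)px * ((y + pad) + (size_t)py * (z + pad));
      std::copy(s, s + nx, t);
    }
}

// stride-1 fast path: shift-and-add over padded buffers (no im2col)
static void conv3d_fw_direct(const double* x, const double* W, const double* b,
                             int nx, int ny, int nz, int cin, int cout, int k,
                             double* out) {
  int pad = (k - 1) / 2;
  int px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  size_t npad = (size_t)px * py * pz;
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> xpad(npad * cin), ypad(npad);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel3d(x + ci * nvox, nx, ny, nz, pad, xpad.data() + ci * npad);
  int K = cin * k * k * k;
  for (int co = 0; co < cout; ++co) {
    std::fill(ypad.begin(), ypad.end(), 0.0);
    int r = 0;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = xpad.data() + ci * npad;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx, ++r) {
            double w = W[co + (size_t)cout * r];
            if (w == 0.0) continue;
            long off = (kx - pad) + (long)px * ((ky - pad) + (long)py * (kz - pad));
            size_t lo = off < 0 ? (size_t)(-off) : 0;
            size_t hi = off > 0 ? npad - off : npad;
            axpy((int)(hi - lo), w, xc + off + lo, ypad.data() + lo);
          }
    }
    (void)K;
    double bc = b[co];
    double* oc = out + (size_t)co * nvox;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double* s = ypad.data() + pad +
          (size_t)px * ((y + pad) + (size_t)py * (z + pad));
        double* t = oc + (size_t)nx * (y + (size_t)ny * z);
        for (int i = 0; i < nx; ++i) t[i] = s[i] + bc;
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                            int k, int stride) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], cin = d.size() > 3 ? d[3] : 1;
  int ox = (nx + stride - 1) / stride, oy = (ny + stride - 1) / stride,
      oz = (nz + stride - 1) / stride;
  int cout = W.nrow();
  NumericVector out((size_t)ox * oy * oz * cout);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  if (stride == 1) {
    conv3d_fw_direct(x.begin(), W.begin(), b.begin(), nx, ny, nz, cin, cout,
                     k, out.begin());
    return out;
  }
  arma::mat colsT = build_colsT3d(x.begin(), nx, ny, nz, cin, k, stride,
                                  ox, oy, oz);
  arma::mat Wm(W.begin(), cout, W.ncol(), false);
  size_t ncol = colsT.n_rows;
  arma::mat Y(out.begin(), ncol, cout, false, true);
  Y = colsT * Wm.t();
  for (int c = 0; c < cout; ++c) Y.col(c) += b[c];
  return out;
}

// stride-1 backward: gx by transposed shift-and-add, gW by offset dots
static void conv3d_bw_direct(const double* x, const double* W,
                             const double* gy, int nx, int ny, int nz,
                             int cin, int cout, int k,
                             double* gx, double* gW, double* gb) {
  int pad = (k - 1) / 2;
  int px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  size_t npad = (size_t)px * py * pz;
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> xpad(npad * cin), gypad(npad * cout), acc(npad);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel3d(x + ci * nvox, nx, ny, nz, pad, xpad.data() + ci * npad);
  for (int co = 0; co < cout; ++co) {
    pad_channel3d(gy + co * nvox, nx, ny, nz, pad, gypad.data() + co * npad);
    double s = 0;
    const double* g = gy + co * nvox;
    for (size_t q = 0; q < nvox; ++q) s += g[q];
    gb[co] = s;
  }
  int r = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = xpad.data() + ci * npad;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          long off = (kx - pad) + (long)px * ((ky - pad) + (long)py * (kz - pad));
          size_t lo = off < 0 ? (size_t)(-off) : 0;
          size_t hi = off > 0 ? npad - off : npad;
          for (int co = 0; co < cout; ++co) {
            const double* gc = gypad.data() + co * npad;
            double w = W[co + (size_t)cout * r];
            // gW: dot of gy with shifted x (pad regions are zero)
            gW[co + (size_t)cout * r] =
              dot((int)(hi - lo), gc + lo, xc + off + lo);
            // gx: gy shifted by -off, weighted
            if (w != 0.0) {
              size_t lo2 = off > 0 ? (size_t)off : 0;
              size_t hi2 = off < 0 ? npad + off : npad;
              axpy((int)(hi2 - lo2), w, gc - off + lo2, acc.data() + lo2);
            }
          }
        }
    // extract core of acc into gx channel ci
    double* oc = gx + (size_t)ci * nvox;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double* s = acc.data() + pad +
          (size_t)px * ((y + pad) + (size_t)py * (z + pad));
        double* t = oc + (size_t)nx * (y + (size_t)ny * z);
        std::copy(s, s + nx, t);
      }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericMatrix W, NumericVector gy,
                   int k, int stride) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], cin = d.size() > 3 ? d[3] : 1;
  IntegerVector dg = gy.attr("dim");
  int ox = dg[0], oy = dg[1], oz = dg[2], cout = dg[3];
  size_t ncol = (size_t)ox * oy * oz;
  if (stride == 1) {
    NumericVector gx((size_t)nx * ny * nz * cin);
    gx.attr("dim") = d;
    NumericMatrix gW(cout, W.ncol());
    NumericVector gb(cout);
    conv3d_bw_direct(x.begin(), W.begin(), gy.begin(), nx, ny, nz, cin, cout,
                     k, gx.begin(), gW.begin(), gb.begin());
    return List::create(Named("gx") = gx, Named("gW") = gW,
                        Named("gb") = gb);
  }
  arma::mat colsT = build_colsT3d(x.begin(), nx, ny, nz, cin, k, stride,
                                  ox, oy, oz);
  arma::mat G(gy.begin(), ncol, cout, false);   // [ncol, cout], no copy
  arma::mat Wm(W.begin(), cout, W.ncol(), false);
  arma::mat gW = (colsT.t() * G).t();
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gcolsT = G * Wm;                    // [ncol, K]
  // col2im scatter-add with line runs
  size_t nvox_in = (size_t)nx * ny * nz;
  NumericVector gx(nvox_in * cin);
  gx.attr("dim") = d;
  double* gxp = gx.begin();
  int pad = (k - 1) / 2;
  size_t r = 0;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = gxp + ci * nvox_in;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          const double* src = gcolsT.colptr(r);
          int xoff = kx - pad;
          for (int zo = 0; zo < oz; ++zo) {
            int z = zo * stride + kz - pad;
            if (z < 0 || z >= nz) continue;
            for (int yo = 0; yo < oy; ++yo) {
              int y = yo * stride + ky - pad;
              if (y < 0 || y >= ny) continue;
              const double* line = src + (size_t)ox * (yo + (size_t)oy * zo);
              double* dst = xc + (size_t)nx * (y + (size_t)ny * z);
              if (stride == 1) {
                int lo = std::max(0, -xoff);
                int hi = std::min(ox, nx - xoff);
                for (int i = lo; i < hi; ++i) dst[i + xoff] += line[i];
              } else {
                for (int xo = 0; xo < ox; ++xo) {
                  int xx = xo * stride + xoff;
                  if (xx >= 0 && xx < nx) dst[xx] += line[xo];
                }
              }
            }
          }
        }
  }
  return List::create(Named("gx") = gx,
                      Named("gW") = wrap(gW),
                      Named("gb") = wrap(gb));
}

// 2D convolution: x [nx,ny,cin]; same conventions as 3D.
static arma::mat build_cols2d(const double* x, int nx, int ny, int cin,
                              int k, int stride, int ox, int oy) {
  int pad = (k - 1) / 2;
  size_t npix_in = (size_t)nx * ny;
  size_t ncol = (size_t)ox * oy;
  size_t K = (size_t)cin * k * k;
  arma::mat cols(K, ncol);
  double* cp = cols.memptr();
  for (int yo = 0; yo < oy; ++yo)
    for (int xo = 0; xo < ox; ++xo) {
      size_t col = (size_t)xo + (size_t)ox * yo;
      double* c = cp + col * K;
      size_t r = 0;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = x + ci * npix_in;
        for (int ky = 0; ky < k; ++ky) {
          int y = yo * stride + ky - pad;
          for (int kx = 0; kx < k; ++kx, ++r) {
            int xx = xo * stride + kx - pad;
            c[r] = (xx < 0 || xx >= nx || y < 0 || y >= ny)
              ? 0.0 : xc[xx + (size_t)nx * y];
          }
        }
      }
    }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                            int k, int stride) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], cin = d.size() > 2 ? d[2] : 1;
  int ox = (nx + stride - 1) / stride, oy = (ny + stride - 1) / stride;
  int cout = W.nrow();
  arma::mat cols = build_cols2d(x.begin(), nx, ny, cin, k, stride, ox, oy);
  arma::mat Wm(W.begin(), cout, W.ncol(), false);
  arma::mat y = Wm * cols;
  size_t ncol = y.n_cols;
  NumericVector out((size_t)cout * ncol);
  out.attr("dim") = IntegerVector::create(ox, oy, cout);
  double* op = out.begin();
  for (int c = 0; c < cout; ++c) {
    double bc = b[c];
    for (size_t i = 0; i < ncol; ++i) op[i + c * ncol] = y(c, i) + bc;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix W, NumericVector gy,
                   int k, int stride) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], cin = d.size() > 2 ? d[2] : 1;
  IntegerVector dg = gy.attr("dim");
  int ox = dg[0], oy = dg[1], cout = dg[2];
  size_t ncol = (size_t)ox * oy;
  arma::mat cols = build_cols2d(x.begin(), nx, ny, cin, k, stride, ox, oy);
  arma::mat G(cout, ncol);
  const double* gp = gy.begin();
  for (int c = 0; c < cout; ++c)
    for (size_t i = 0; i < ncol; ++i) G(c, i) = gp[i + c * ncol];
  arma::mat Wm(W.begin(), cout, W.ncol(), false);
  arma::mat gW = G * cols.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat gcols = Wm.t() * G;
  size_t npix_in = (size_t)nx * ny;
  NumericVector gx(npix_in * cin);
  gx.attr("dim") = d;
  double* gxp = gx.begin();
  int pad = (k - 1) / 2;
  size_t K = (size_t)cin * k * k;
  const double* gc = gcols.memptr();
  for (int yo = 0; yo < oy; ++yo)
    for (int xo = 0; xo < ox; ++xo) {
      size_t col = (size_t)xo + (size_t)ox * yo;
      const double* c = gc + col * K;
      size_t r = 0;
      for (int ci = 0; ci < cin; ++ci) {
        double* xc = gxp + ci * npix_in;
        for (int ky = 0; ky < k; ++ky) {
          int y = yo * stride + ky - pad;
          for (int kx = 0; kx < k; ++kx, ++r) {
            int xx = xo * stride + kx - pad;
            if (xx >= 0 && xx < nx && y >= 0 && y < ny)
              xc[xx + (size_t)nx * y] += c[r];
          }
        }
      }
    }
  return List::create(Named("gx") = gx,
                      Named("gW") = wrap(gW),
                      Named("gb") = wrap(gb));
}

// ---------------------------------------------------------------------------
// 2x2(x2) max pooling with argmax indices (1-based, into the flattened
// spatial-and-channel input) so the backward pass is a scatter.
// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], nc = d.size() > 3 ? d[3] : 1;
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  size_t nout = (size_t)ox * oy * oz * nc;
  NumericVector y(nout);
  IntegerVector idx(nout);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < nc; ++c) {
    size_t coff = (size_t)c * nx * ny * nz;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++o) {
          double best = -1e300; size_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t ii = coff + (2*i+dx) + (size_t)nx * ((2*j+dy) + (size_t)ny * (2*k+dz));
                if (xp[ii] > best) { best = xp[ii]; bi = ii; }
              }
          y[o] = best; idx[o] = (int)(bi + 1);
        }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
List cpp_maxpool2d_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nc = d.size() > 2 ? d[2] : 1;
  int ox = nx / 2, oy = ny / 2;
  size_t nout = (size_t)ox * oy * nc;
  NumericVector y(nout);
  IntegerVector idx(nout);
  y.attr("dim") = IntegerVector::create(ox, oy, nc);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < nc; ++c) {
    size_t coff = (size_t)c * nx * ny;
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++o) {
        double best = -1e300; size_t bi = 0;
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            size_t ii = coff + (2*i+dx) + (size_t)nx * (2*j+dy);
            if (xp[ii] > best) { best = xp[ii]; bi = ii; }
          }
        y[o] = best; idx[o] = (int)(bi + 1);
      }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// ---------------------------------------------------------------------------
// Trilinear resize of a (multi-channel) 3D array with align-corners mapping
// in_coord = out_idx * (n_in - 1) / (n_out - 1); plus its adjoint, needed
// for backpropagation through up/down-sampling layers.
static void resize_weights(int n_in, int n_out, std::vector<int>& i0,
                           std::vector<double>& f) {
  i0.resize(n_out); f.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double c = (n_out == 1) ? 0.0 : (double)o * (n_in - 1) / (n_out - 1);
    int ii = (int)std::floor(c);
    if (ii > n_in - 2) ii = n_in - 2;
    if (ii < 0) ii = 0;
    double ff = (n_in == 1) ? 0.0 : c - ii;
    i0[o] = ii; f[o] = ff;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector out_dim) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2], nc = d.size() > 3 ? d[3] : 1;
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  std::vector<int> xi, yi, zi; std::vector<double> xf, yf, zf;
  resize_weights(nx, ox, xi, xf);
  resize_weights(ny, oy, yi, yf);
  resize_weights(nz, oz, zi, zf);
  size_t nout = (size_t)ox * oy * oz * nc;
  NumericVector out(nout);
  if (d.size() > 3)
    out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  else
    out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < nc; ++c) {
    const double* v = xp + (size_t)c * nx * ny * nz;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++o) {
          int x0 = xi[i], y0 = yi[j], z0 = zi[k];
          double fx = xf[i], fy = yf[j], fz = zf[k];
          int x1 = std::min(x0+1, nx-1), y1 = std::min(y0+1, ny-1), z1 = std::min(z0+1, nz-1);
          #define V(a,b,cc) v[(a) + (size_t)nx * ((b) + (size_t)ny * (cc))]
          double c00 = V(x0,y0,z0)*(1-fx) + V(x1,y0,z0)*fx;
          double c10 = V(x0,y1,z0)*(1-fx) + V(x1,y1,z0)*fx;
          double c01 = V(x0,y0,z1)*(1-fx) + V(x1,y0,z1)*fx;
          double c11 = V(x0,y1,z1)*(1-fx) + V(x1,y1,z1)*fx;
          #undef V
          out[o] = (c00*(1-fy) + c10*fy)*(1-fz) + (c01*(1-fy) + c11*fy)*fz;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize3d_adj(NumericVector g, IntegerVector in_dim) {
  IntegerVector dg = g.attr("dim");
  int ox = dg[0], oy = dg[1], oz = dg[2], nc = dg.size() > 3 ? dg[3] : 1;
  int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  std::vector<int> xi, yi, zi; std::vector<double> xf, yf, zf;
  resize_weights(nx, ox, xi, xf);
  resize_weights(ny, oy, yi, yf);
  resize_weights(nz, oz, zi, zf);
  size_t nin = (size_t)nx * ny * nz * nc;
  NumericVector out(nin);
  if (dg.size() > 3)
    out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  else
    out.attr("dim") = IntegerVector::create(nx, ny, nz);
  double* op = out.begin();
  const double* gp = g.begin();
  size_t o = 0;
  for (int c = 0; c < nc; ++c) {
    double* v = op + (size_t)c * nx * ny * nz;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++o) {
          int x0 = xi[i], y0 = yi[j], z0 = zi[k];
          double fx = xf[i], fy = yf[j], fz = zf[k];
          int x1 = std::min(x0+1, nx-1), y1 = std::min(y0+1, ny-1), z1 = std::min(z0+1, nz-1);
          double gv = gp[o];
          #define A(a,b,cc,w) v[(a) + (size_t)nx * ((b) + (size_t)ny * (cc))] += gv * (w)
          A(x0,y0,z0,(1-fx)*(1-fy)*(1-fz)); A(x1,y0,z0,fx*(1-fy)*(1-fz));
          A(x0,y1,z0,(1-fx)*fy*(1-fz));     A(x1,y1,z0,fx*fy*(1-fz));
          A(x0,y0,z1,(1-fx)*(1-fy)*fz);     A(x1,y0,z1,fx*(1-fy)*fz);
          A(x0,y1,z1,(1-fx)*fy*fz);         A(x1,y1,z1,fx*fy*fz);
          #undef A
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with edge clamping; sigma per axis in voxels.
static void smooth_axis(std::vector<double>& buf, double* v, int nx, int ny,
                        int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2*r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i+r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i+r];
  }
  for (auto& w : ker) w /= s;
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int na = n[axis];
  size_t sa = stride[axis];
  int b1 = axis == 0 ? 1 : 0;
  int b2 = axis == 2 ? 1 : 2;
  buf.resize(na);
  for (int j2 = 0; j2 < n[b2]; ++j2)
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      size_t base = stride[b1] * j1 + stride[b2] * j2;
      for (int i = 0; i < na; ++i) buf[i] = v[base + sa * i];
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        for (int kk = -r; kk <= r; ++kk)
          acc += ker[kk+r] * buf[clampi(i + kk, 0, na - 1)];
        v[base + sa * i] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector x, NumericVector sigma_vox) {
  IntegerVector d = x.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out = clone(x);
  std::vector<double> buf;
  smooth_axis(buf, out.begin(), nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(buf, out.begin(), nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(buf, out.begin(), nx, ny, nz, 2, sigma_vox[2]);
  return out;
}

// ---------------------------------------------------------------------------
// Parzen-window mutual information with per-voxel window truncation: only
// bins whose Gaussian weight is non-negligible (within ~10 sigma of the
// value) enter; weights are renormalized over the window, matching the
// dense soft-histogram definition to machine precision for narrow kernels.
// Returns MI (nats) and optionally d MI / d a.
// [[Rcpp::export]]
List cpp_mi_grad(NumericVector a, NumericVector b, int B, double bw,
                 bool with_grad) {
  size_t n = a.size();
  double sigma = bw / B;
  int R = std::max(1, (int)std::ceil(10.0 * bw));
  if (2 * R + 1 > B) R = (B - 1) / 2 + 1;
  std::vector<double> centres(B);
  for (int k = 0; k < B; ++k) centres[k] = (k + 0.5) / B;
  auto window = [&](double x, int& klo, int& khi) {
    int k1 = (int)std::lround(x * B - 0.5);
    klo = std::max(0, k1 - R);
    khi = std::min(B - 1, k1 + R);
  };
  const int WMAX = 2 * (B + 1);
  std::vector<double> wa(WMAX), wb(WMAX);
  arma::mat p(B, B, arma::fill::zeros);
  for (size_t i = 0; i < n; ++i) {
    double x = clampd(a[i], 0.0, 1.0), y = clampd(b[i], 0.0, 1.0);
    int alo, ahi, blo, bhi;
    window(x, alo, ahi); window(y, blo, bhi);
    double sa = 0, sb = 0;
    for (int k = alo; k <= ahi; ++k) {
      double d = (x - centres[k]) / sigma;
      wa[k - alo] = std::exp(-0.5 * d * d); sa += wa[k - alo];
    }
    for (int l = blo; l <= bhi; ++l) {
      double d = (y - centres[l]) / sigma;
      wb[l - blo] = std::exp(-0.5 * d * d); sb += wb[l - blo];
    }
    for (int k = alo; k <= ahi; ++k)
      for (int l = blo; l <= bhi; ++l)
        p(k, l) += (wa[k - alo] / sa) * (wb[l - blo] / sb);
  }
  p /= (double)n;
  arma::vec pa = arma::sum(p, 1), pb = arma::sum(p, 0).t();
  const double eps = 1e-12;
  arma::mat G(B, B);
  double value = 0;
  for (int k = 0; k < B; ++k)
    for (int l = 0; l < B; ++l) {
      G(k, l) = std::log(p(k, l) + eps) - std::log(pa[k] + eps) -
                std::log(pb[l] + eps);
      value += p(k, l) * G(k, l);
    }
  if (!with_grad)
    return List::create(Named("value") = value);
  NumericVector grad(n);
  double inv = 1.0 / ((double)n * sigma * sigma);
  for (size_t i = 0; i < n; ++i) {
    double x = clampd(a[i], 0.0, 1.0), y = clampd(b[i], 0.0, 1.0);
    int alo, ahi, blo, bhi;
    window(x, alo, ahi); window(y, blo, bhi);
    double sa = 0, sb = 0;
    for (int k = alo; k <= ahi; ++k) {
      double d = (x - centres[k]) / sigma;
      wa[k - alo] = std::exp(-0.5 * d * d); sa += wa[k - alo];
    }
    for (int l = blo; l <= bhi; ++l) {
      double d = (y - centres[l]) / sigma;
      wb[l - blo] = std::exp(-0.5 * d * d); sb += wb[l - blo];
    }
    double abar = 0;
    for (int k = alo; k <= ahi; ++k) abar += (wa[k - alo] / sa) * centres[k];
    double g = 0;
    for (int k = alo; k <= ahi; ++k) {
      double m = 0;
      for (int l = blo; l <= bhi; ++l) m += (wb[l - blo] / sb) * G(k, l);
      g += (wa[k - alo] / sa) * (centres[k] - abar) * m;
    }
    grad[i] = g * inv;
  }
  return List::create(Named("value") = value, Named("grad") = grad);
}

// diffusion regulariser: sum over the 9 Jacobian entries of the mean
// squared forward difference (per mm); value and gradient w.r.t. the field
// [[Rcpp::export]]
List cpp_smooth_penalty_grad(NumericVector field, NumericVector spacing,
                             bool with_grad) {
  IntegerVector d = field.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector grad(with_grad ? 3 * nvox : 0);
  if (with_grad) grad.attr("dim") = d;
  double total = 0;
  int nn[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int c = 0; c < 3; ++c) {
    const double* u = field.begin() + c * nvox;
    double* g = with_grad ? grad.begin() + c * nvox : nullptr;
    for (int ax = 0; ax < 3; ++ax) {
      if (nn[ax] <= 1) continue;
      size_t sa = stride[ax];
      size_t cnt = nvox / nn[ax] * (nn[ax] - 1);
      double inv_sp = 1.0 / spacing[ax];
      double ssum = 0;
      size_t idx = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i, ++idx) {
            int pos = ax == 0 ? i : (ax == 1 ? j : k);
            if (pos >= nn[ax] - 1) continue;
            double diff = (u[idx + sa] - u[idx]) * inv_sp;
            ssum += diff * diff;
            if (with_grad) {
              double coeff = 2.0 * diff / ((double)cnt) * inv_sp;
              g[idx + sa] += coeff;
              g[idx] -= coeff;
            }
          }
      total += ssum / (double)cnt;
    }
  }
  if (with_grad)
    return List::create(Named("value") = total, Named("grad") = grad);
  return List::create(Named("value") = total);
}
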