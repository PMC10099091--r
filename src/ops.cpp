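// Low-level dense 3D kernels for the spatial-transformer registration stack.
// Layout convention: a C-channel field over a (d1, d2, d3) voxel grid is a
// numeric vector indexed i + d1*(j + d2*(k + d3*c)) — i.e. an R array with
// dim c(d1, d2, d3, C). All backward passes are exact adjoints/gradients of
// their forward counterparts (checked by finite differences in the tests).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------- conv3d ---

// 'same' zero-padded 3D convolution (cross-correlation) with odd kernel k.
// w layout: (((co*cin + ci)*k + az)*k + ay)*k + ax, offsets centred at k/2.
// Line-buffered: each output row is accumulated in a stack buffer so the
// output is written once, keeping the kernel compute-bound.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims, int cin,
                             NumericVector w, NumericVector b, int cout,
                             int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int p = k / 2;
  NumericVector y(n * cout);
  std::vector<double> acc(d1);
  for (int co = 0; co < cout; ++co) {
    double* yc = &y[0] + n * co;
    const double bc = b[co];
    for (int l = 0; l < d3; ++l) {
      for (int j = 0; j < d2; ++j) {
        for (int i = 0; i < d1; ++i) acc[i] = bc;
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = &x[0] + n * ci;
          for (int az = 0; az < k; ++az) {
            const int lz = l + az - p;
            if (lz < 0 || lz >= d3) continue;
            for (int ay = 0; ay < k; ++ay) {
              const int jy = j + ay - p;
              if (jy < 0 || jy >= d2) continue;
              const double* xl = xc + (R_xlen_t)d1 * (jy + (R_xlen_t)d2 * lz);
              const double* wl =
                &w[(((R_xlen_t)(co * cin + ci) * k + az) * k + ay) * k];
              for (int ax = 0; ax < k; ++ax) {
                const int dx = ax - p;
                const double wv = wl[ax];
                const int i0 = std::max(0, -dx), i1 = std::min(d1, d1 - dx);
                const double* xp = xl + dx;
                for (int i = i0; i < i1; ++i) acc[i] += wv * xp[i];
              }
            }
          }
        }
        double* yp = yc + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
        for (int i = 0; i < d1; ++i) yp[i] = acc[i];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector gy, IntegerVector dims,
                    int cin, int cout, NumericVector w, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int p = k / 2;
  NumericVector gx(n * cin), gw(w.size()), gb(cout);
  // One pass per (co, output line): accumulate the filter gradient as row
  // dot products and scatter the data gradient into the (cached) input-side
  // rows touched by that output row.
  for (int co = 0; co < cout; ++co) {
    const double* gyc = &gy[0] + n * co;
    double bacc = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) bacc += gyc[t];
    gb[co] = bacc;
    for (int l = 0; l < d3; ++l) {
      for (int j = 0; j < d2; ++j) {
        const double* gyl = gyc + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = &x[0] + n * ci;
          double* gxc = &gx[0] + n * ci;
          for (int az = 0; az < k; ++az) {
            const int lz = l + az - p;
            if (lz < 0 || lz >= d3) continue;
            for (int ay = 0; ay < k; ++ay) {
              const int jy = j + ay - p;
              if (jy < 0 || jy >= d2) continue;
              const R_xlen_t off = (R_xlen_t)d1 * (jy + (R_xlen_t)d2 * lz);
              const double* xl = xc + off;
              double* gxl = gxc + off;
              double* gwl =
                &gw[(((R_xlen_t)(co * cin + ci) * k + az) * k + ay) * k];
              const double* wl =
                &w[(((R_xlen_t)(co * cin + ci) * k + az) * k + ay) * k];
              for (int ax = 0; ax < k; ++ax) {
                const int dx = ax - p;
                const int i0 = std::max(0, -dx), i1 = std::min(d1, d1 - dx);
                const double wv = wl[ax];
                const double* xp = xl + dx;
                double* gxp = gxl + dx;
                double gwacc = 0.0;
                for (int i = i0; i < i1; ++i) {
                  const double g = gyl[i];
                  gwacc += g * xp[i];
                  gxp[i] += wv * g;
                }
                gwl[ax] += gwacc;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// --------------------------------------------------------------- maxpool ---

// 2x2x2 max pooling; all dims must be even.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector dims, int c) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3, on = (R_xlen_t)o1 * o2 * o3;
  NumericVector y(on * c);
  IntegerVector am(on * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = &x[0] + n * ch;
    double* yc = &y[0] + on * ch;
    int* amc = &am[0] + on * ch;
    for (int l = 0; l < o3; ++l)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i) {
          double best = -HUGE_VAL; R_xlen_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t xi = (R_xlen_t)(2 * i + dx) +
                  (R_xlen_t)d1 * ((2 * j + dy) + (R_xlen_t)d2 * (2 * l + dz));
                if (xc[xi] > best) { best = xc[xi]; bidx = xi; }
              }
          const R_xlen_t oi = (R_xlen_t)i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * l);
          yc[oi] = best;
          amc[oi] = (int)bidx;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector argmax,
                                IntegerVector dims, int c) {
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  const R_xlen_t on = gy.size() / c;
  NumericVector gx(n * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* gyc = &gy[0] + on * ch;
    const int* amc = &argmax[0] + on * ch;
    double* gxc = &gx[0] + n * ch;
    for (R_xlen_t t = 0; t < on; ++t) gxc[amc[t]] += gyc[t];
  }
  return gx;
}

// ---------------------------------------------------------------- resize ---

// Trilinear resize with zero-origin scaling: source coordinate of output
// voxel i along an axis is i * (in_dim / out_dim), clamped to the source
// grid. Constant and linear fields are reproduced exactly away from the
// clamped trailing edge.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector dims, int c,
                           IntegerVector odims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = odims[0], o2 = odims[1], o3 = odims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3, on = (R_xlen_t)o1 * o2 * o3;
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector y(on * c);
  std::vector<int> i0(o1), i1v(o1), j0(o2), j1v(o2), l0(o3), l1v(o3);
  std::vector<double> fi(o1), fj(o2), fl(o3);
  for (int i = 0; i < o1; ++i) {
    double s = std::min(std::max(i * s1, 0.0), (double)(d1 - 1));
    i0[i] = (int)std::floor(s); i1v[i] = std::min(i0[i] + 1, d1 - 1); fi[i] = s - i0[i];
  }
  for (int j = 0; j < o2; ++j) {
    double s = std::min(std::max(j * s2, 0.0), (double)(d2 - 1));
    j0[j] = (int)std::floor(s); j1v[j] = std::min(j0[j] + 1, d2 - 1); fj[j] = s - j0[j];
  }
  for (int l = 0; l < o3; ++l) {
    double s = std::min(std::max(l * s3, 0.0), (double)(d3 - 1));
    l0[l] = (int)std::floor(s); l1v[l] = std::min(l0[l] + 1, d3 - 1); fl[l] = s - l0[l];
  }
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = &x[0] + n * ch;
    double* yc = &y[0] + on * ch;
    for (int l = 0; l < o3; ++l)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i) {
          const double fx = fi[i], fy = fj[j], fz = fl[l];
          double v = 0.0;
          for (int cz = 0; cz < 2; ++cz) {
            const int zz = cz ? l1v[l] : l0[l];
            const double wz = cz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int cy = 0; cy < 2; ++cy) {
              const int yy = cy ? j1v[j] : j0[j];
              const double wy = cy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int cx = 0; cx < 2; ++cx) {
                const int xx = cx ? i1v[i] : i0[i];
                const double wx = cx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                v += wz * wy * wx *
                  xc[(R_xlen_t)xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz)];
              }
            }
          }
          yc[(R_xlen_t)i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * l)] = v;
        }
  }
  return y;
}

// Adjoint of cpp_resize3d (scatter of interpolation weights).
// [[Rcpp::export]]
NumericVector cpp_resize3d_adjoint(NumericVector gy, IntegerVector odims,
                                   int c, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = odims[0], o2 = odims[1], o3 = odims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3, on = (R_xlen_t)o1 * o2 * o3;
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector gx(n * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* gyc = &gy[0] + on * ch;
    double* gxc = &gx[0] + n * ch;
    for (int l = 0; l < o3; ++l) {
      double sz = std::min(std::max(l * s3, 0.0), (double)(d3 - 1));
      const int z0 = (int)std::floor(sz), z1 = std::min(z0 + 1, d3 - 1);
      const double fz = sz - z0;
      for (int j = 0; j < o2; ++j) {
        double sy = std::min(std::max(j * s2, 0.0), (double)(d2 - 1));
        const int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, d2 - 1);
        const double fy = sy - y0;
        for (int i = 0; i < o1; ++i) {
          double sx = std::min(std::max(i * s1, 0.0), (double)(d1 - 1));
          const int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, d1 - 1);
          const double fx = sx - x0;
          const double g = gyc[(R_xlen_t)i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * l)];
          if (g == 0.0) continue;
          for (int cz = 0; cz < 2; ++cz) {
            const int zz = cz ? z1 : z0; const double wz = cz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int cy = 0; cy < 2; ++cy) {
              const int yy = cy ? y1 : y0; const double wy = cy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int cx = 0; cx < 2; ++cx) {
                const int xx = cx ? x1 : x0; const double wx = cx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                gxc[(R_xlen_t)xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz)] +=
                  g * wz * wy * wx;
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// ------------------------------------------------------------------ warp ---

// Backward-mapping warp: out(x) = v(clamp(x + u(x))). u is a 3-component
// field in voxel units, layout [pos + n*comp]. mode 0 = trilinear, 1 =
// nearest neighbour.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector v, IntegerVector dims, NumericVector u,
                       int mode) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector y(n);
  for (int l = 0; l < d3; ++l)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t t = (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
        double sx = i + u[t], sy = j + u[t + n], sz = l + u[t + 2 * n];
        sx = std::min(std::max(sx, 0.0), (double)(d1 - 1));
        sy = std::min(std::max(sy, 0.0), (double)(d2 - 1));
        sz = std::min(std::max(sz, 0.0), (double)(d3 - 1));
        if (mode == 1) {
          const int xi = clampi((int)std::floor(sx + 0.5), 0, d1 - 1);
          const int yi = clampi((int)std::floor(sy + 0.5), 0, d2 - 1);
          const int zi = clampi((int)std::floor(sz + 0.5), 0, d3 - 1);
          y[t] = v[(R_xlen_t)xi + (R_xlen_t)d1 * (yi + (R_xlen_t)d2 * zi)];
          continue;
        }
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                  z0 = (int)std::floor(sz);
        const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
                  z1 = std::min(z0 + 1, d3 - 1);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int cz = 0; cz < 2; ++cz) {
          const int zz = cz ? z1 : z0; const double wz = cz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int cy = 0; cy < 2; ++cy) {
            const int yy = cy ? y1 : y0; const double wy = cy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            for (int cx = 0; cx < 2; ++cx) {
              const int xx = cx ? x1 : x0; const double wx = cx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              acc += wz * wy * wx *
                v[(R_xlen_t)xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz)];
            }
          }
        }
        y[t] = acc;
      }
  return y;
}

// Gradient of the trilinear warp with respect to the displacement field.
// Where the sampling point is clamped along an axis the partial derivative
// along that axis is zero.
// [[Rcpp::export]]
NumericVector cpp_warp_bwd_u(NumericVector v, IntegerVector dims,
                             NumericVector u, NumericVector gy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector gu(3 * n);
  for (int l = 0; l < d3; ++l)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t t = (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
        const double g = gy[t];
        if (g == 0.0) continue;
        double sx = i + u[t], sy = j + u[t + n], sz = l + u[t + 2 * n];
        const bool cxed = sx <= 0.0 || sx >= d1 - 1;
        const bool cyed = sy <= 0.0 || sy >= d2 - 1;
        const bool czed = sz <= 0.0 || sz >= d3 - 1;
        sx = std::min(std::max(sx, 0.0), (double)(d1 - 1));
        sy = std::min(std::max(sy, 0.0), (double)(d2 - 1));
        sz = std::min(std::max(sz, 0.0), (double)(d3 - 1));
        const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                  z0 = (int)std::floor(sz);
        const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
                  z1 = std::min(z0 + 1, d3 - 1);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double c[2][2][2];
        for (int cz = 0; cz < 2; ++cz)
          for (int cy = 0; cy < 2; ++cy)
            for (int cx = 0; cx < 2; ++cx)
              c[cz][cy][cx] = v[(R_xlen_t)(cx ? x1 : x0) +
                (R_xlen_t)d1 * ((cy ? y1 : y0) + (R_xlen_t)d2 * (cz ? z1 : z0))];
        // interpolate pairwise differences
        const double dvx =
          (1 - fz) * ((1 - fy) * (c[0][0][1] - c[0][0][0]) + fy * (c[0][1][1] - c[0][1][0])) +
          fz * ((1 - fy) * (c[1][0][1] - c[1][0][0]) + fy * (c[1][1][1] - c[1][1][0]));
        const double dvy =
          (1 - fz) * ((1 - fx) * (c[0][1][0] - c[0][0][0]) + fx * (c[0][1][1] - c[0][0][1])) +
          fz * ((1 - fx) * (c[1][1][0] - c[1][0][0]) + fx * (c[1][1][1] - c[1][0][1]));
        const double dvz =
          (1 - fy) * ((1 - fx) * (c[1][0][0] - c[0][0][0]) + fx * (c[1][0][1] - c[0][0][1])) +
          fy * ((1 - fx) * (c[1][1][0] - c[0][1][0]) + fx * (c[1][1][1] - c[0][1][1]));
        if (!cxed) gu[t] = g * dvx;
        if (!cyed) gu[t + n] = g * dvy;
        if (!czed) gu[t + 2 * n] = g * dvz;
      }
  return gu;
}

// ------------------------------------------------- shifts and box filter ---

// Edge-clamped integer shift: y(x) = x(clamp(x + r)).
// [[Rcpp::export]]
NumericVector cpp_shift_clamp(NumericVector x, IntegerVector dims,
                              IntegerVector r) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int rx = r[0], ry = r[1], rz = r[2];
  NumericVector y((R_xlen_t)d1 * d2 * d3);
  for (int l = 0; l < d3; ++l) {
    const int lz = clampi(l + rz, 0, d3 - 1);
    for (int j = 0; j < d2; ++j) {
      const int jy = clampi(j + ry, 0, d2 - 1);
      const double* xp = &x[0] + (R_xlen_t)d1 * (jy + (R_xlen_t)d2 * lz);
      double* yp = &y[0] + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
      for (int i = 0; i < d1; ++i) yp[i] = xp[clampi(i + rx, 0, d1 - 1)];
    }
  }
  return y;
}

// Adjoint of cpp_shift_clamp (scatter-add onto the clamped source voxel).
// [[Rcpp::export]]
NumericVector cpp_shift_clamp_adjoint(NumericVector g, IntegerVector dims,
                                      IntegerVector r) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int rx = r[0], ry = r[1], rz = r[2];
  NumericVector y((R_xlen_t)d1 * d2 * d3);
  for (int l = 0; l < d3; ++l) {
    const int lz = clampi(l + rz, 0, d3 - 1);
    for (int j = 0; j < d2; ++j) {
      const int jy = clampi(j + ry, 0, d2 - 1);
      double* yp = &y[0] + (R_xlen_t)d1 * (jy + (R_xlen_t)d2 * lz);
      const double* gp = &g[0] + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * l);
      for (int i = 0; i < d1; ++i) yp[clampi(i + rx, 0, d1 - 1)] += gp[i];
    }
  }
  return y;
}

// Sliding cube sum of half-width 'radius' (zero outside the grid);
// separable, self-adjoint.
static void axis_boxsum(std::vector<double>& buf, int d1, int d2, int d3,
                        int radius, int axis) {
  std::vector<double> line;
  const int dims[3] = {d1, d2, d3};
  const int dlen = dims[axis];
  line.resize(dlen);
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  R_xlen_t nouter = (R_xlen_t)d1 * d2 * d3 / dlen;
  for (R_xlen_t o = 0; o < nouter; ++o) {
    // compute base index of this line
    R_xlen_t rem = o, base = 0, mul = 1;
    for (int a = 0; a < 3; ++a) {
      if (a == axis) { mul *= dims[a]; continue; }
      R_xlen_t idx = rem % dims[a];
      rem /= dims[a];
      base += idx * mul;
      mul *= dims[a];
    }
    for (int t = 0; t < dlen; ++t) line[t] = buf[base + (R_xlen_t)t * stride];
    double acc = 0.0;
    for (int t = 0; t <= std::min(radius, dlen - 1); ++t) acc += line[t];
    for (int t = 0; t < dlen; ++t) {
      buf[base + (R_xlen_t)t * stride] = acc;
      const int add = t + radius + 1, rm = t - radius;
      if (add < dlen) acc += line[add];
      if (rm >= 0) acc -= line[rm];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, IntegerVector dims, int radius) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<double> buf(x.begin(), x.end());
  if (radius > 0) {
    axis_boxsum(buf, d1, d2, d3, radius, 0);
    axis_boxsum(buf, d1, d2, d3, radius, 1);
    axis_boxsum(buf, d1, d2, d3, radius, 2);
  }
  return NumericVector(buf.begin(), buf.end());
}

// ------------------------------------------------------ axis differences ---

// First/second finite differences of a (possibly multi-channel) field along
// one axis. order 1: central differences interior, one-sided at borders.
// order 2: three-point second difference interior, zero at border planes.
// adjoint = 1 computes the exact transpose of the same linear operator.
// [[Rcpp::export]]
NumericVector cpp_axis_diff(NumericVector x, IntegerVector dims, int nc,
                            int axis, int order, int adjoint) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  const int dlen = d[axis];
  NumericVector y(n * nc);
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= d[a];
  const R_xlen_t nouter = n / dlen;
  std::vector<double> line(dlen), out(dlen);
  for (int ch = 0; ch < nc; ++ch) {
    const double* xc = &x[0] + n * ch;
    double* yc = &y[0] + n * ch;
    for (R_xlen_t o = 0; o < nouter; ++o) {
      R_xlen_t rem = o, base = 0, mul = 1;
      for (int a = 0; a < 3; ++a) {
        if (a == axis) { mul *= d[a]; continue; }
        R_xlen_t idx = rem % d[a]; rem /= d[a];
        base += idx * mul; mul *= d[a];
      }
      for (int t = 0; t < dlen; ++t) line[t] = xc[base + (R_xlen_t)t * stride];
      std::fill(out.begin(), out.end(), 0.0);
      if (dlen >= 2) {
        if (order == 1 && !adjoint) {
          out[0] = line[1] - line[0];
          out[dlen - 1] = line[dlen - 1] - line[dlen - 2];
          for (int t = 1; t < dlen - 1; ++t)
            out[t] = 0.5 * (line[t + 1] - line[t - 1]);
        } else if (order == 1 && adjoint) {
          out[0] -= line[0];
          out[1] += line[0];
          out[dlen - 2] -= line[dlen - 1];
          out[dlen - 1] += line[dlen - 1];
          for (int t = 1; t < dlen - 1; ++t) {
            out[t - 1] -= 0.5 * line[t];
            out[t + 1] += 0.5 * line[t];
          }
        } else if (order == 2 && !adjoint) {
          for (int t = 1; t < dlen - 1; ++t)
            out[t] = line[t - 1] - 2.0 * line[t] + line[t + 1];
        } else {
          for (int t = 1; t < dlen - 1; ++t) {
            out[t - 1] += line[t];
            out[t] -= 2.0 * line[t];
            out[t + 1] += line[t];
          }
        }
      }
      for (int t = 0; t < dlen; ++t) yc[base + (R_xlen_t)t * stride] = out[t];
    }
  }
  return y;
}

// ------------------------------------------------------ gaussian smooth ----

// Separable Gaussian smoothing, kernel truncated at 3 sigma, renormalized at
// the edges (filter weights outside the grid are dropped and the remaining
// weights rescaled to sum to one).
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector x, IntegerVector dims,
                                  NumericVector sigma) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> buf(x.begin(), x.end());
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * rad + 1);
    for (int t = -rad; t <= rad; ++t)
      kern[t + rad] = std::exp(-0.5 * (t / s) * (t / s));
    const int dlen = d[axis];
    R_xlen_t stride = 1;
    for (int a = 0; a < axis; ++a) stride *= d[a];
    const R_xlen_t nouter = (R_xlen_t)d[0] * d[1] * d[2] / dlen;
    std::vector<double> line(dlen), out(dlen);
    for (R_xlen_t o = 0; o < nouter; ++o) {
      R_xlen_t rem = o, base = 0, mul = 1;
      for (int a = 0; a < 3; ++a) {
        if (a == axis) { mul *= d[a]; continue; }
        R_xlen_t idx = rem % d[a]; rem /= d[a];
        base += idx * mul; mul *= d[a];
      }
      for (int t = 0; t < dlen; ++t) line[t] = buf[base + (R_xlen_t)t * stride];
      for (int t = 0; t < dlen; ++t) {
        double acc = 0.0, wsum = 0.0;
        const int lo = std::max(0, t - rad), hi = std::min(dlen - 1, t + rad);
        for (int q = lo; q <= hi; ++q) {
          const double w = kern[q - t + rad];
          acc += w * line[q];
          wsum += w;
        }
        out[t] = acc / wsum;
      }
      for (int t = 0; t < dlen; ++t) buf[base + (R_xlen_t)t * stride] = out[t];
    }
  }
  return NumericVector(buf.begin(), buf.end());
}

// ----------------------------------------------------- point sampling ------

// Trilinear sampling of a C-channel field at arbitrary (0-based) voxel
// coordinates, edge-clamped. pts is m x 3 (column-major).
// [[Rcpp::export]]
NumericMatrix cpp_sample_trilinear(NumericVector x, IntegerVector dims, int c,
                                   NumericMatrix pts) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int m = pts.nrow();
  NumericMatrix out(m, c);
  for (int p = 0; p < m; ++p) {
    double sx = std::min(std::max(pts(p, 0), 0.0), (double)(d1 - 1));
    double sy = std::min(std::max(pts(p, 1), 0.0), (double)(d2 - 1));
    double sz = std::min(std::max(pts(p, 2), 0.0), (double)(d3 - 1));
    const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
              z0 = (int)std::floor(sz);
    const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1),
              z1 = std::min(z0 + 1, d3 - 1);
    const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
    for (int ch = 0; ch < c; ++ch) {
      const double* xc = &x[0] + n * ch;
      double acc = 0.0;
      for (int cz = 0; cz < 2; ++cz) {
        const int zz = cz ? z1 : z0; const double wz = cz ? fz : 1.0 - fz;
        if (wz == 0.0) continue;
        for (int cy = 0; cy < 2; ++cy) {
          const int yy = cy ? y1 : y0; const double wy = cy ? fy : 1.0 - fy;
          if (wy == 0.0) continue;
          for (int cx = 0; cx < 2; ++cx) {
            const int xx = cx ? x1 : x0; const double wx = cx ? fx : 1.0 - fx;
            if (wx == 0.0) continue;
            acc += wz * wy * wx *
              xc[(R_xlen_t)xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz)];
          }
        }
      }
      out(p, ch) = acc;
    }
  }
  return out;
}
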