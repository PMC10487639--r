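#ifndef TOMATCH_SPLINE_H
#define TOMATCH_SPLINE_H

#include <cmath>
#include <vector>
#include <cstddef>

// Cubic B-spline prefilter (Unser's recursive filter, single pole
// z1 = sqrt(3) - 2) and interpolation kernels for volume rotation.
// Boundary handling: mirror for the prefilter, zero outside for sampling.

namespace tomatch {

inline double bspline_pole() { return std::sqrt(3.0) - 2.0; }

// In-place causal/anticausal filtering of one line with stride.
inline void prefilter_line(double* c, int n, std::ptrdiff_t stride) {
  if (n < 2) return;
  const double z = bspline_pole();
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);  // overall gain = 6
  // causal initialization: truncated sum with mirror boundary
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double zk = z, sum = c[0];
  for (int k = 1; k < horizon; ++k) {
    sum += zk * c[(std::ptrdiff_t)k * stride];
    zk *= z;
  }
  c[0] = lambda * sum;
  for (int k = 1; k < n; ++k)
    c[(std::ptrdiff_t)k * stride] =
        lambda * c[(std::ptrdiff_t)k * stride] + z * c[(std::ptrdiff_t)(k - 1) * stride];
  // anticausal initialization
  c[(std::ptrdiff_t)(n - 1) * stride] =
      (z / (z * z - 1.0)) *
      (c[(std::ptrdiff_t)(n - 1) * stride] + z * c[(std::ptrdiff_t)(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[(std::ptrdiff_t)k * stride] =
        z * (c[(std::ptrdiff_t)(k + 1) * stride] - c[(std::ptrdiff_t)k * stride]);
}

// Convert a volume (nx fastest) to B-spline coefficients in place.
inline void bspline_prefilter3(double* v, int nx, int ny, int nz) {
  // x lines
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilter_line(v + (std::ptrdiff_t)nx * (y + (std::ptrdiff_t)ny * z), nx, 1);
  // y lines
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilter_line(v + x + (std::ptrdiff_t)nx * ny * z, ny, nx);
  // z lines
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilter_line(v + x + (std::ptrdiff_t)nx * y, nz, (std::ptrdiff_t)nx * ny);
}

inline void bspline_weights(double u, double w[4]) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (4.0 - 6.0 * u2 + 3.0 * u3) / 6.0;
  w[2] = (1.0 + 3.0 * u + 3.0 * u2 - 3.0 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// mirror (whole-sample symmetric) index reflection, matching the
// prefilter's boundary assumption
inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return i < n ? i : period - i;
}

inline double coef_at(const double* c, int nx, int ny, int nz, int x, int y, int z) {
  x = mirror_idx(x, nx);
  y = mirror_idx(y, ny);
  z = mirror_idx(z, nz);
  return c[x + (std::ptrdiff_t)nx * (y + (std::ptrdiff_t)ny * z)];
}

// Sample prefiltered coefficients at (tx, ty, tz); zero outside [0, n-1].
inline double sample_bspline3(const double* c, int nx, int ny, int nz,
                              double tx, double ty, double tz) {
  if (tx < 0.0 || ty < 0.0 || tz < 0.0 ||
      tx > nx - 1.0 || ty > ny - 1.0 || tz > nz - 1.0)
    return 0.0;
  const int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
  double wx[4], wy[4], wz[4];
  bspline_weights(tx - ix, wx);
  bspline_weights(ty - iy, wy);
  bspline_weights(tz - iz, wz);
  double s = 0.0;
  for (int k = 0; k < 4; ++k) {
    const int z = iz - 1 + k;
    double sy = 0.0;
    for (int j = 0; j < 4; ++j) {
      const int y = iy - 1 + j;
      double sx = 0.0;
      for (int i = 0; i < 4; ++i)
        sx += wx[i] * coef_at(c, nx, ny, nz, ix - 1 + i, y, z);
      sy += wy[j] * sx;
    }
    s += wz[k] * sy;
  }
  return s;
}

// Trilinear sampling on raw values; zero outside [0, n-1].
inline double sample_linear3(const double* v, int nx, int ny, int nz,
                             double tx, double ty, double tz) {
  if (tx < 0.0 || ty < 0.0 || tz < 0.0 ||
      tx > nx - 1.0 || ty > ny - 1.0 || tz > nz - 1.0)
    return 0.0;
  const int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
  const double ux = tx - ix, uy = ty - iy, uz = tz - iz;
  double s = 0.0;
  for (int k = 0; k < 2; ++k)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i) {
        const double w = (i ? ux : 1.0 - ux) * (j ? uy : 1.0 - uy) * (k ? uz : 1.0 - uz);
        if (w != 0.0)
          s += w * coef_at(v, nx, ny, nz, ix + i, iy + j, iz + k);
      }
  return s;
}

// Active rotation of a cubic volume about floor(n/2): out(x) = in(R^T (x-c) + c).
// interp: 0 = linear (on raw values), 1 = cubic b-spline (on coefficients).
inline void rotate_volume_raw(const double* src, double* dst, int n,
                              const double R[9], int interp) {
  const double c = std::floor(n / 2.0);
  // inverse of a rotation matrix is its transpose; R is column-major 3x3
  const double r11 = R[0], r21 = R[1], r31 = R[2];
  const double r12 = R[3], r22 = R[4], r32 = R[5];
  const double r13 = R[6], r23 = R[7], r33 = R[8];
  std::ptrdiff_t idx = 0;
  for (int z = 0; z < n; ++z) {
    const double pz = z - c;
    for (int y = 0; y < n; ++y) {
      const double py = y - c;
      for (int x = 0; x < n; ++x, ++idx) {
        const double px = x - c;
        // R^T * p
        const double qx = r11 * px + r21 * py + r31 * pz + c;
        const double qy = r12 * px + r22 * py + r32 * pz + c;
        const double qz = r13 * px + r23 * py + r33 * pz + c;
        dst[idx] = interp == 1 ? sample_bspline3(src, n, n, n, qx, qy, qz)
                               : sample_linear3(src, n, n, n, qx, qy, qz);
      }
    }
  }
}

}  // namespace tomatch

#endif
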