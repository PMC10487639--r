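#include <Rcpp.h>
#include <fftw3.h>
#include <vector>
#include <complex>
#include <cstring>
#include <cmath>
#include "spline.h"

using namespace Rcpp;

typedef std::complex<double> cplxd;

// Scoring engine for masked, locally normalized cross-correlation (LCC)
// of a template against a tomogram over an orientation list. All FFTs go
// through FFTW; the tomogram transform and (for spherical masks) the
// local standard deviation are computed once and reused per orientation.

namespace {

struct R2C3 {
  int nx, ny, nz, nxh;
  size_t n, nc;
  double* real;
  fftw_complex* cplx;
  fftw_plan fwd, inv;
  R2C3(int nx_, int ny_, int nz_, unsigned flags)
      : nx(nx_), ny(ny_), nz(nz_), nxh(nx_ / 2 + 1),
        n((size_t)nx_ * ny_ * nz_), nc((size_t)nxh * ny_ * nz_) {
    real = fftw_alloc_real(n);
    cplx = fftw_alloc_complex(nc);
    // FFTW is row-major: pass (nz, ny, nx) so x is the fastest axis.
    fwd = fftw_plan_dft_r2c_3d(nz, ny, nx, real, cplx, flags);
    inv = fftw_plan_dft_c2r_3d(nz, ny, nx, cplx, real, flags);
  }
  ~R2C3() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(inv);
    fftw_free(real);
    fftw_free(cplx);
  }
};

// Index map for embedding an L^3 box into the big volume with a circular
// shift of -c, so that the box center lands on voxel (0,0,0).
std::vector<size_t> embed_indices(int L, int nx, int ny, int nz) {
  const int c = L / 2;
  std::vector<size_t> idx((size_t)L * L * L);
  size_t b = 0;
  for (int z = 0; z < L; ++z) {
    const int gz = ((z - c) % nz + nz) % nz;
    for (int y = 0; y < L; ++y) {
      const int gy = ((y - c) % ny + ny) % ny;
      for (int x = 0; x < L; ++x, ++b) {
        const int gx = ((x - c) % nx + nx) % nx;
        idx[b] = (size_t)gx + (size_t)nx * (gy + (size_t)ny * gz);
      }
    }
  }
  return idx;
}

// Multiply half-spectrum by a full-size real filter evaluated at the
// stored (unshifted) frequency indices.
void apply_wedge_half(fftw_complex* spec, const double* wedge, int L) {
  const int nxh = L / 2 + 1;
  size_t s = 0;
  for (int z = 0; z < L; ++z)
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < nxh; ++x, ++s) {
        const double w = wedge[(size_t)x + (size_t)L * (y + (size_t)L * z)];
        spec[s][0] *= w;
        spec[s][1] *= w;
      }
}

// Local mean and sd of v under mask at every position, via FFT.
// mean(x) = sum_y M0(y) v(y+x) / P with M0 the center-shifted mask.
void local_moments(R2C3& big, const std::vector<cplxd>& FV,
                   const std::vector<cplxd>& FV2,
                   const double* mask, int L, double P,
                   std::vector<double>& mean, std::vector<double>& sd) {
  const size_t n = big.n, nc = big.nc;
  std::vector<size_t> eidx = embed_indices(L, big.nx, big.ny, big.nz);
  std::fill(big.real, big.real + n, 0.0);
  const size_t nb = (size_t)L * L * L;
  for (size_t b = 0; b < nb; ++b) big.real[eidx[b]] = mask[b];
  fftw_execute(big.fwd);
  std::vector<cplxd> FM(nc);
  std::memcpy(FM.data(), big.cplx, nc * sizeof(fftw_complex));

  const double scale = 1.0 / ((double)n * P);
  mean.resize(n);
  sd.resize(n);
  for (size_t i = 0; i < nc; ++i) {  // conj(FM) * FV
    big.cplx[i][0] = FM[i].real() * FV[i].real() + FM[i].imag() * FV[i].imag();
    big.cplx[i][1] = FM[i].real() * FV[i].imag() - FM[i].imag() * FV[i].real();
  }
  fftw_execute(big.inv);
  for (size_t i = 0; i < n; ++i) mean[i] = big.real[i] * scale;
  for (size_t i = 0; i < nc; ++i) {  // conj(FM) * FV2
    big.cplx[i][0] = FM[i].real() * FV2[i].real() + FM[i].imag() * FV2[i].imag();
    big.cplx[i][1] = FM[i].real() * FV2[i].imag() - FM[i].imag() * FV2[i].real();
  }
  fftw_execute(big.inv);
  for (size_t i = 0; i < n; ++i) {
    const double var = big.real[i] * scale - mean[i] * mean[i];
    sd[i] = var > 0.0 ? std::sqrt(var) : 0.0;
  }
}

double global_sd(const double* v, size_t n) {
  double m = 0.0;
  for (size_t i = 0; i < n; ++i) m += v[i];
  m /= (double)n;
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) s += (v[i] - m) * (v[i] - m);
  return std::sqrt(s / (double)n);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_rotate")]]
NumericVector cpp_rotate(NumericVector vol, IntegerVector dims,
                         NumericVector rotmat, int interp) {
  const int n = dims[0];
  if (dims[1] != n || dims[2] != n) stop("volume must be cubic");
  if (rotmat.size() != 9) stop("rotation matrix must be 3x3");
  std::vector<double> src(vol.begin(), vol.end());
  if (interp == 1) tomatch::bspline_prefilter3(src.data(), n, n, n);
  NumericVector out(vol.size());
  double R[9];
  for (int i = 0; i < 9; ++i) R[i] = rotmat[i];
  tomatch::rotate_volume_raw(src.data(), REAL(out), n, R, interp);
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cpp_local_std")]]
List cpp_local_std(NumericVector tomo, IntegerVector dimv,
                   NumericVector mask, IntegerVector dimt) {
  const int NX = dimv[0], NY = dimv[1], NZ = dimv[2];
  const int L = dimt[0];
  if (dimt[1] != L || dimt[2] != L) stop("mask must be cubic");
  double P = 0.0;
  for (R_xlen_t i = 0; i < mask.size(); ++i) P += mask[i];
  if (P <= 0.0) stop("mask sums to zero");
  R2C3 big(NX, NY, NZ, FFTW_ESTIMATE);
  std::copy(tomo.begin(), tomo.end(), big.real);
  fftw_execute(big.fwd);
  std::vector<cplxd> FV(big.nc);
  std::memcpy(FV.data(), big.cplx, big.nc * sizeof(fftw_complex));
  for (size_t i = 0; i < big.n; ++i) big.real[i] = tomo[i] * tomo[i];
  fftw_execute(big.fwd);
  std::vector<cplxd> FV2(big.nc);
  std::memcpy(FV2.data(), big.cplx, big.nc * sizeof(fftw_complex));
  std::vector<double> mean, sd;
  local_moments(big, FV, FV2, REAL(mask), L, P, mean, sd);
  NumericVector meanv(mean.begin(), mean.end()), sdv(sd.begin(), sd.end());
  meanv.attr("dim") = dimv;
  sdv.attr("dim") = dimv;
  return List::create(_["mean"] = meanv, _["sd"] = sdv);
}

// [[Rcpp::export(name = ".cpp_run_match")]]
List cpp_run_match(NumericVector tomo, IntegerVector dimv,
                   NumericVector tmpl, NumericVector mask, IntegerVector dimt,
                   Nullable<NumericVector> wedge, NumericMatrix rot,
                   bool spherical, int interp, double std_floor_rel,
                   int verbose_every) {
  const int NX = dimv[0], NY = dimv[1], NZ = dimv[2];
  const int L = dimt[0];
  if (dimt[1] != L || dimt[2] != L) stop("template box must be cubic");
  if (NX < L || NY < L || NZ < L) stop("template box exceeds tomogram");
  const int n_orient = rot.ncol();
  if (n_orient < 1) stop("empty orientation set");
  const size_t n = (size_t)NX * NY * NZ;
  const size_t nb = (size_t)L * L * L;
  const int c = L / 2;

  // plans first (planning may scribble on buffers), data after
  R2C3 big(NX, NY, NZ, FFTW_MEASURE);
  R2C3 box(L, L, L, FFTW_ESTIMATE);

  std::copy(tomo.begin(), tomo.end(), big.real);
  fftw_execute(big.fwd);
  std::vector<cplxd> FV(big.nc);
  std::memcpy(FV.data(), big.cplx, big.nc * sizeof(fftw_complex));
  // second spectrum feeds the local sd (once if spherical, else per orientation)
  for (size_t i = 0; i < n; ++i) big.real[i] = tomo[i] * tomo[i];
  fftw_execute(big.fwd);
  std::vector<cplxd> FV2(big.nc);
  std::memcpy(FV2.data(), big.cplx, big.nc * sizeof(fftw_complex));

  const double floor_sd = std_floor_rel * global_sd(REAL(tomo), n);
  std::vector<size_t> eidx = embed_indices(L, NX, NY, NZ);

  // template spline coefficients (or raw values for linear interpolation)
  std::vector<double> tco(tmpl.begin(), tmpl.end());
  if (interp == 1) tomatch::bspline_prefilter3(tco.data(), L, L, L);

  NumericVector wkeep;  // keep the SEXP alive
  const double* wptr = nullptr;
  if (wedge.isNotNull()) {
    wkeep = NumericVector(wedge);
    wptr = REAL(wkeep);
  }

  // per-position 1 / (n * P * sigma_V); zero encodes the flat-region floor
  std::vector<double> inv_denom(n);
  double P = 0.0;
  for (size_t b = 0; b < nb; ++b) P += mask[b];
  if (P <= 0.0) stop("mask sums to zero");
  if (spherical) {
    std::vector<double> mean, sd;
    local_moments(big, FV, FV2, REAL(mask), L, P, mean, sd);
    for (size_t i = 0; i < n; ++i)
      inv_denom[i] = sd[i] > floor_sd ? 1.0 / ((double)n * P * sd[i]) : 0.0;
  }

  std::vector<double> trot(nb), tw(nb), mrot;
  std::vector<double> best(n, -2.0);
  std::vector<int> bidx(n, 0);

  for (int o = 0; o < n_orient; ++o) {
    double R[9];
    for (int i = 0; i < 9; ++i) R[i] = rot(i, o);
    tomatch::rotate_volume_raw(tco.data(), trot.data(), L, R, interp);

    // missing-wedge weighting of the rotated template (tomogram-frame PSF)
    if (wptr) {
      std::copy(trot.begin(), trot.end(), box.real);
      fftw_execute(box.fwd);
      apply_wedge_half(box.cplx, wptr, L);
      fftw_execute(box.inv);
      for (size_t b = 0; b < nb; ++b) tw[b] = box.real[b] / (double)nb;
    } else {
      std::copy(trot.begin(), trot.end(), tw.data());
    }

    const double* mcur = REAL(mask);
    double Pcur = P;
    if (!spherical) {
      mrot.resize(nb);
      double Rm[9];
      for (int i = 0; i < 9; ++i) Rm[i] = rot(i, o);
      tomatch::rotate_volume_raw(REAL(mask), mrot.data(), L, Rm, 0);
      Pcur = 0.0;
      for (size_t b = 0; b < nb; ++b) {
        if (mrot[b] < 0.0) mrot[b] = 0.0;
        if (mrot[b] > 1.0) mrot[b] = 1.0;
        Pcur += mrot[b];
      }
      if (Pcur <= 0.0) continue;
      mcur = mrot.data();
      std::vector<double> mean, sd;
      local_moments(big, FV, FV2, mcur, L, Pcur, mean, sd);
      for (size_t i = 0; i < n; ++i)
        inv_denom[i] = sd[i] > floor_sd ? 1.0 / ((double)n * Pcur * sd[i]) : 0.0;
    }

    // normalize template under the mask: Tm = M * (Tw - mu), sigma_T
    double mu = 0.0;
    for (size_t b = 0; b < nb; ++b) mu += mcur[b] * tw[b];
    mu /= Pcur;
    double ssq = 0.0;
    for (size_t b = 0; b < nb; ++b) {
      const double d = tw[b] - mu;
      ssq += mcur[b] * d * d;
    }
    const double sigT = std::sqrt(ssq / Pcur);
    if (!(sigT > 1e-12)) {
      if (n_orient == 1) stop("degenerate template: zero variance under mask");
      continue;
    }

    std::fill(big.real, big.real + n, 0.0);
    for (size_t b = 0; b < nb; ++b)
      big.real[eidx[b]] = mcur[b] * (tw[b] - mu);
    fftw_execute(big.fwd);
    for (size_t i = 0; i < big.nc; ++i) {  // conj(F_T) * F_V
      const double re = big.cplx[i][0] * FV[i].real() + big.cplx[i][1] * FV[i].imag();
      const double im = big.cplx[i][0] * FV[i].imag() - big.cplx[i][1] * FV[i].real();
      big.cplx[i][0] = re;
      big.cplx[i][1] = im;
    }
    fftw_execute(big.inv);

    const double inv_sigT = 1.0 / sigT;
    for (size_t i = 0; i < n; ++i) {
      const double s = big.real[i] * inv_denom[i] * inv_sigT;
      if (s > best[i]) {
        best[i] = s;
        bidx[i] = o;
      }
    }

    if (verbose_every > 0 && (o + 1) % verbose_every == 0)
      Rcout << "orientation " << (o + 1) << "/" << n_orient << "\n";
    if ((o & 31) == 0) Rcpp::checkUserInterrupt();
  }

  // wrap-around margin: half the template box on every face is invalid
  const int lo = c, hix = NX - L + c, hiy = NY - L + c, hiz = NZ - L + c;
  for (int z = 0; z < NZ; ++z)
    for (int y = 0; y < NY; ++y)
      for (int x = 0; x < NX; ++x) {
        if (x < lo || y < lo || z < lo || x > hix || y > hiy || z > hiz) {
          const size_t i = (size_t)x + (size_t)NX * (y + (size_t)NY * z);
          best[i] = -1.0;
          bidx[i] = 0;
        }
      }

  NumericVector scores(best.begin(), best.end());
  IntegerVector angles(bidx.begin(), bidx.end());
  scores.attr("dim") = dimv;
  angles.attr("dim") = dimv;
  return List::create(_["scores"] = scores, _["angle_index"] = angles,
                      _["margin_lo"] = lo, _["margin_hi"] = L - c - 1);
}

// LCCmax restricted to a set of positions: identical score definition as
// .cpp_run_match, but the correlation is evaluated directly at m voxels
// instead of everywhere, which is far cheaper for large orientation sets.
// [[Rcpp::export(name = ".cpp_score_at_positions")]]
List cpp_score_at_positions(NumericVector tomo, IntegerVector dimv,
                            NumericVector tmpl, NumericVector mask,
                            IntegerVector dimt, Nullable<NumericVector> wedge,
                            NumericMatrix rot, IntegerMatrix pos, int interp,
                            double std_floor_rel) {
  const int NX = dimv[0], NY = dimv[1], NZ = dimv[2];
  const int L = dimt[0];
  const int c = L / 2;
  const int m = pos.nrow();
  const int n_orient = rot.ncol();
  const size_t n = (size_t)NX * NY * NZ;
  const size_t nb = (size_t)L * L * L;

  // gather the tomogram values under each position's box once
  std::vector<double> vbox((size_t)m * nb);
  for (int p = 0; p < m; ++p) {
    const int px = pos(p, 0), py = pos(p, 1), pz = pos(p, 2);
    if (px < c || py < c || pz < c || px > NX - L + c || py > NY - L + c ||
        pz > NZ - L + c)
      stop("position lies in the invalid margin");
    size_t b = 0;
    for (int z = 0; z < L; ++z)
      for (int y = 0; y < L; ++y)
        for (int x = 0; x < L; ++x, ++b) {
          const size_t vi = (size_t)(px + x - c) +
                            (size_t)NX * ((py + y - c) + (size_t)NY * (pz + z - c));
          vbox[(size_t)p * nb + b] = tomo[vi];
        }
  }

  double P = 0.0;
  for (size_t b = 0; b < nb; ++b) P += mask[b];
  if (P <= 0.0) stop("mask sums to zero");
  const double floor_sd = std_floor_rel * global_sd(REAL(tomo), n);

  // local sd under the (unrotated, assumed spherical) mask per position
  std::vector<double> sigV(m);
  for (int p = 0; p < m; ++p) {
    double s1 = 0.0, s2 = 0.0;
    const double* v = &vbox[(size_t)p * nb];
    for (size_t b = 0; b < nb; ++b) {
      s1 += mask[b] * v[b];
      s2 += mask[b] * v[b] * v[b];
    }
    const double mean = s1 / P;
    const double var = s2 / P - mean * mean;
    sigV[p] = var > 0.0 ? std::sqrt(var) : 0.0;
  }

  std::vector<double> tco(tmpl.begin(), tmpl.end());
  if (interp == 1) tomatch::bspline_prefilter3(tco.data(), L, L, L);
  NumericVector wkeep;
  const double* wptr = nullptr;
  if (wedge.isNotNull()) {
    wkeep = NumericVector(wedge);
    wptr = REAL(wkeep);
  }
  R2C3 box(L, L, L, FFTW_ESTIMATE);

  std::vector<double> trot(nb), tw(nb);
  std::vector<double> best(m, -2.0);
  std::vector<int> bidx(m, 0);

  for (int o = 0; o < n_orient; ++o) {
    double R[9];
    for (int i = 0; i < 9; ++i) R[i] = rot(i, o);
    tomatch::rotate_volume_raw(tco.data(), trot.data(), L, R, interp);
    if (wptr) {
      std::copy(trot.begin(), trot.end(), box.real);
      fftw_execute(box.fwd);
      apply_wedge_half(box.cplx, wptr, L);
      fftw_execute(box.inv);
      for (size_t b = 0; b < nb; ++b) tw[b] = box.real[b] / (double)nb;
    } else {
      std::copy(trot.begin(), trot.end(), tw.data());
    }
    double mu = 0.0;
    for (size_t b = 0; b < nb; ++b) mu += mask[b] * tw[b];
    mu /= P;
    double ssq = 0.0;
    for (size_t b = 0; b < nb; ++b) {
      const double d = tw[b] - mu;
      ssq += mask[b] * d * d;
    }
    const double sigT = std::sqrt(ssq / P);
    if (!(sigT > 1e-12)) continue;

    for (int p = 0; p < m; ++p) {
      if (sigV[p] <= floor_sd) {
        if (0.0 > best[p]) {
          best[p] = 0.0;
          bidx[p] = o;
        }
        continue;
      }
      const double* v = &vbox[(size_t)p * nb];
      double num = 0.0;
      for (size_t b = 0; b < nb; ++b) num += mask[b] * (tw[b] - mu) * v[b];
      const double s = num / (P * sigT * sigV[p]);
      if (s > best[p]) {
        best[p] = s;
        bidx[p] = o;
      }
    }
    if ((o & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["scores"] = NumericVector(best.begin(), best.end()),
                      _["angle_index"] = IntegerVector(bidx.begin(), bidx.end()));
}
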