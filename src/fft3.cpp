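#include <Rcpp.h>
#include <fftw3.h>

using namespace Rcpp;

// Complex-to-complex 3D FFT via FFTW. dims = c(nx, ny, nz) with x the
// fastest-varying axis (R array layout). Inverse transform is normalized
// by 1/(nx*ny*nz) so that fft3(fft3(x), inverse = TRUE) == x.
// [[Rcpp::export(name = ".cpp_fft3")]]
ComplexVector cpp_fft3(ComplexVector x, IntegerVector dims, bool inverse) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)x.size() != n) stop("array length does not match dims");

  fftw_complex* buf = fftw_alloc_complex(n);
  // FFTW is row-major; passing (nz, ny, nx) makes x the fastest axis.
  fftw_plan p = fftw_plan_dft_3d(nz, ny, nx, buf, buf,
                                 inverse ? FFTW_BACKWARD : FFTW_FORWARD,
                                 FFTW_ESTIMATE);
  for (size_t i = 0; i < n; ++i) {
    buf[i][0] = x[i].r;
    buf[i][1] = x[i].i;
  }
  fftw_execute(p);
  ComplexVector out(n);
  const double scale = inverse ? 1.0 / (double)n : 1.0;
  for (size_t i = 0; i < n; ++i) {
    out[i].r = buf[i][0] * scale;
    out[i].i = buf[i][1] * scale;
  }
  fftw_destroy_plan(p);
  fftw_free(buf);
  out.attr("dim") = dims;
  return out;
}
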