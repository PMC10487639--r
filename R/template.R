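#' Relativistic electron wavelength
#'
#' De Broglie wavelength of an electron accelerated through `voltage`
#' kilovolts, with the relativistic correction, from CODATA constants.
#'
#' @param voltage acceleration voltage in kV (> 0).
#' @return wavelength in angstrom.
#' @examples
#' electron_wavelength(200)  # ~0.02508 A
#' @export
electron_wavelength <- function(voltage) {
  if (!is.numeric(voltage) || any(!is.finite(voltage)) || any(voltage <= 0))
    stop("`voltage` must be positive (kV)", call. = FALSE)
  h <- 6.62607015e-34
  m0 <- 9.1093837015e-31
  e <- 1.602176634e-19
  c0 <- 299792458
  u <- voltage * 1e3
  lambda_m <- h / sqrt(2 * m0 * e * u * (1 + e * u / (2 * m0 * c0^2)))
  lambda_m * 1e10
}

#' CTF parameter set
#'
#' @param defocus defocus in micrometre, positive for underfocus.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in `[0, 1]`.
#' @return list of class `ctf_params`.
#' @examples
#' ctf_params(defocus = 3, voltage = 200, cs = 2.7, amplitude_contrast = 0.08)
#' @export
ctf_params <- function(defocus, voltage, cs, amplitude_contrast) {
  stopifnot(is.finite(defocus), voltage > 0, is.finite(cs),
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(defocus = defocus, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

ctf_phase <- function(k, ctf) {
  lambda <- electron_wavelength(ctf$voltage)
  dz <- ctf$defocus * 1e4   # um -> A
  cs <- ctf$cs * 1e7        # mm -> A
  pi * lambda * dz * k^2 - (pi / 2) * cs * lambda^3 * k^4
}

#' Contrast transfer function modulation
#'
#' Standard weak-phase CTF,
#' `-(sqrt(1 - A^2) * sin(chi) + A * cos(chi))` with
#' `chi(k) = pi * lambda * dz * k^2 - pi/2 * Cs * lambda^3 * k^4`,
#' underfocus positive, no envelope or phase plate. With
#' `truncate_after_first_zero` the curve is set to 0 for all frequencies
#' beyond its first zero crossing.
#'
#' @param k spatial frequency in 1/angstrom (vector allowed, `k >= 0`).
#' @param ctf a [ctf_params] object.
#' @param truncate_after_first_zero logical.
#' @return unitless modulation values, `|value| <= 1`.
#' @export
ctf_modulation <- function(k, ctf, truncate_after_first_zero = FALSE) {
  stopifnot(inherits(ctf, "ctf_params"), all(k >= 0))
  a <- ctf$amplitude_contrast
  chi <- ctf_phase(k, ctf)
  val <- -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
  if (truncate_after_first_zero) {
    k0 <- ctf_first_zero(ctf)
    if (is.finite(k0)) val[k > k0] <- 0
  }
  val
}

#' First zero crossing of the CTF
#'
#' Smallest `k > 0` where the full (amplitude-contrast-shifted) CTF
#' crosses zero, located by bracketing and root refinement. Returns `NA`
#' if no zero exists below `k_max`.
#'
#' @inheritParams ctf_modulation
#' @param k_max upper search bound in 1/angstrom.
#' @return frequency in 1/angstrom, or `NA`.
#' @export
ctf_first_zero <- function(ctf, k_max = 1) {
  a <- ctf$amplitude_contrast
  f <- function(k) sqrt(1 - a^2) * sin(ctf_phase(k, ctf)) + a * cos(ctf_phase(k, ctf))
  ks <- seq(0, k_max, length.out = 20001)[-1]
  vals <- f(ks)
  # CTF(0) = -A <= 0, i.e. f(0) >= 0: the first zero is the first sign flip
  s0 <- sign(f(1e-9))
  if (s0 == 0) s0 <- 1
  flip <- which(sign(vals) != s0 & sign(vals) != 0)
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  lo <- if (i == 1) 1e-9 else ks[i - 1]
  uniroot(f, c(lo, ks[i]), tol = 1e-12)$root
}

#' Build a matching template from a density map
#'
#' Processing chain at the input voxel size: the map's Fourier transform
#' is multiplied radially by the (optionally truncated) CTF, then by a
#' soft-edged low-pass filter (raised-cosine edge two Fourier voxels
#' wide); the result is Fourier-cropped to the output voxel size and
#' centered in a cubic box. Mean subtraction and normalization happen
#' later, inside matching.
#'
#' @param map cubic [density_volume] at the fine voxel size.
#' @param output_voxel target voxel size in angstrom (`>=` the input
#'   voxel size); the realized size is `input * n / round(n * input /
#'   output)` and is recorded on the result.
#' @param box_size output box edge in voxels (default: the resampled
#'   size).
#' @param ctf optional [ctf_params] for CTF modulation.
#' @param lowpass optional low-pass cutoff in angstrom (e.g. 40).
#' @param truncate_ctf set the CTF to zero beyond its first zero
#'   crossing.
#' @return [density_volume] template.
#' @export
build_template <- function(map, output_voxel = map$voxel_size, box_size = NULL,
                           ctf = NULL, lowpass = NULL, truncate_ctf = TRUE) {
  stopifnot(is_density_volume(map))
  d <- dim(map$data)
  if (length(unique(d)) != 1L) stop("`map` must be cubic", call. = FALSE)
  n <- d[1]
  vi <- map$voxel_size
  if (output_voxel < vi - 1e-9)
    stop("`output_voxel` must be >= the input voxel size", call. = FALSE)
  nyq <- 1 / (2 * vi)
  if (!is.null(lowpass)) {
    if (1 / lowpass > nyq + 1e-12)
      stop("low-pass cutoff beyond the input Nyquist frequency", call. = FALSE)
  }

  ff <- fft3(map$data)
  kx <- fft_freq_index(n) / (n * vi)
  k2 <- outer(kx^2, kx^2, "+")
  kmag <- sqrt(outer(k2, kx^2, "+"))  # n^3 array of |k| in 1/A

  if (!is.null(ctf)) {
    ff <- ff * ctf_modulation(as.vector(kmag), ctf,
                              truncate_after_first_zero = truncate_ctf)
  }
  if (!is.null(lowpass)) {
    kc <- 1 / lowpass
    w <- 2 / (n * vi)  # raised-cosine edge, 2 Fourier voxels wide
    t <- (kc + w / 2 - kmag) / w
    filt <- ifelse(t >= 1, 1, ifelse(t <= 0, 0, 0.5 - 0.5 * cos(pi * t)))
    ff <- ff * as.vector(filt)
  }
  dim(ff) <- c(n, n, n)

  n_out <- as.integer(round(n * vi / output_voxel))
  if (n_out < 1) stop("output voxel too large for this map", call. = FALSE)
  vo <- vi * n / n_out
  if (n_out < n) {
    keep <- (-(n_out %/% 2)):(n_out - n_out %/% 2 - 1)
    oi <- keep %% n + 1
    ni <- keep %% n_out + 1
    fc <- array(0 + 0i, c(n_out, n_out, n_out))
    fc[ni, ni, ni] <- ff[oi, oi, oi]
    out <- Re(fft3(fc, inverse = TRUE)) * (n_out^3 / n^3)
  } else {
    out <- Re(fft3(ff, inverse = TRUE))
  }
  dim(out) <- c(n_out, n_out, n_out)

  if (is.null(box_size)) box_size <- n_out
  if (box_size < n_out)
    stop("`box_size` too small for the resampled map (needs >= ", n_out, ")",
         call. = FALSE)
  if (box_size > n_out) {
    big <- array(0, c(box_size, box_size, box_size))
    off <- box_size %/% 2 - n_out %/% 2
    idx <- (off + 1):(off + n_out)
    big[idx, idx, idx] <- out
    out <- big
  }
  density_volume(out, voxel_size = vo)
}

#' Soft-edged spherical mask
#'
#' Value 1 inside the sphere, Gaussian fall-off with `soft_edge_sigma`
#' voxels outside, exactly 0 beyond `radius + 3 * sigma`. Centered on
#' voxel `floor(box/2)` (0-based).
#'
#' @param box_size cubic box edge in voxels.
#' @param diameter sphere diameter in angstrom.
#' @param voxel_size voxel size in angstrom.
#' @param soft_edge_sigma Gaussian edge width in voxels (0 = hard).
#' @return [density_volume] with values in `[0, 1]`, plus attributes
#'   `diameter` and `soft_edge_sigma`.
#' @export
build_spherical_mask <- function(box_size, diameter, voxel_size,
                                 soft_edge_sigma = 1.5) {
  if (diameter > box_size * voxel_size)
    stop("sphere larger than the box", call. = FALSE)
  r <- (diameter / 2) / voxel_size
  c0 <- box_size %/% 2
  ax <- (0:(box_size - 1)) - c0
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  dist <- sqrt(d2)
  m <- array(0, dim(dist))
  m[dist <= r] <- 1
  if (soft_edge_sigma > 0) {
    edge <- dist > r & dist <= r + 3 * soft_edge_sigma
    m[edge] <- exp(-((dist[edge] - r)^2) / (2 * soft_edge_sigma^2))
  }
  v <- density_volume(m, voxel_size)
  attr(v, "diameter") <- diameter
  attr(v, "soft_edge_sigma") <- soft_edge_sigma
  v
}

#' Missing-wedge half-angles from a tilt range
#'
#' A symmetric tilt series `+/- t` degrees leaves a double wedge of
#' unmeasured Fourier space with half-angle `90 - t` on each side.
#'
#' @param tilt_range length-2 tilt range in degrees, e.g. `c(-51, 51)`.
#' @return length-2 wedge angles in degrees `(low side, high side)`.
#' @examples
#' missing_wedge_angles(c(-51, 51))  # 39 39
#' @export
missing_wedge_angles <- function(tilt_range) {
  stopifnot(length(tilt_range) == 2, all(abs(tilt_range) <= 90))
  c(90 - abs(min(tilt_range)), 90 - abs(max(tilt_range)))
}

#' Binary missing-wedge Fourier mask
#'
#' Value 1 where the Fourier direction was measured by the tilt series
#' (tilt axis along y, beam along z), 0 inside the missing double wedge.
#' A voxel with in-plane angle `a = atan2(kz, kx)` (folded to
#' `(-90, 90]`) passes when `|a| <= 90 - wedge angle` on its side; the
#' `kx = kz = 0` line always passes. The mask depends on `|k|` geometry
#' only and is Hermitian-symmetric by construction.
#'
#' @param dims length-3 volume dimensions in voxels.
#' @param angles length-2 wedge half-angles in degrees (low, high);
#'   `c(39, 39)` corresponds to a `+/-51` degree tilt range.
#' @param smooth optional transition width in degrees (0 = sharp binary).
#' @return [density_volume] Fourier mask in unshifted FFT layout.
#' @export
build_wedge_mask <- function(dims, angles = c(39, 39), smooth = 0) {
  stopifnot(length(dims) == 3, length(angles) == 2,
            all(angles >= 0), all(angles <= 90))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  kx <- fft_freq_index(nx) / nx
  kz <- fft_freq_index(nz) / nz
  ang <- atan2(rep(kz, each = nx), rep(kx, times = nz)) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang < -90] <- ang[ang < -90] + 180
  lim <- ifelse(ang >= 0, 90 - angles[2], 90 - angles[1])
  if (smooth > 0) {
    t <- (lim - abs(ang)) / smooth + 0.5
    val <- ifelse(t >= 1, 1, ifelse(t <= 0, 0, 0.5 - 0.5 * cos(pi * t)))
  } else {
    val <- as.numeric(abs(ang) <= lim)
  }
  val[rep(kx == 0, times = nz) & rep(kz == 0, each = nx)] <- 1
  m2 <- matrix(val, nrow = nx, ncol = nz)  # (kx, kz) plane
  arr <- aperm(array(m2, c(nx, nz, ny)), c(1, 3, 2))
  density_volume(arr, 1)
}
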