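#' Density volume
#'
#' A 3D scalar grid with an isotropic voxel size in angstrom. Carries
#' tomograms, templates, masks, and score maps. The first array axis (x)
#' is the fastest-varying one, matching the MRC axis order; indexing is
#' 0-based at serialization boundaries and 1-based inside R, with voxel
#' (0,0,0) at the grid corner.
#'
#' @param data numeric 3D array; all values must be finite.
#' @param voxel_size edge length of a voxel in angstrom (> 0).
#' @return An object of class `density_volume`.
#' @examples
#' v <- density_volume(array(rnorm(8^3), c(8, 8, 8)), voxel_size = 13.8)
#' dim(v)
#' @export
density_volume <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  if (!all(is.finite(data))) stop("volume values must be finite", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "density_volume")
}

#' @export
dim.density_volume <- function(x) dim(x$data)

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g Å/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

is_density_volume <- function(x) inherits(x, "density_volume")

as_volume_data <- function(v) {
  if (is_density_volume(v)) v$data else v
}

#' Unnormalized/normalized 3D FFT of an array
#'
#' Thin wrapper over the FFTW backend; the inverse transform is scaled by
#' 1/N so that `fft3(fft3(x), inverse = TRUE)` recovers `x`.
#'
#' @param x numeric or complex 3D array.
#' @param inverse logical; compute the backward transform.
#' @return complex 3D array of the same dimensions.
#' @keywords internal
fft3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (length(d) != 3L) stop("`x` must be a 3D array", call. = FALSE)
  .cpp_fft3(as.complex(x), as.integer(d), isTRUE(inverse))
}

# centered frequency indices for an axis of length n (cycles per sample
# when divided by n); layout matches the unshifted FFT output.
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k
}
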