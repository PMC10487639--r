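# run code under a private, restorable RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic reference template
#'
#' An asymmetric smooth blob built from randomly placed Gaussian lobes
#' inside a sphere, windowed to zero at the stated diameter. The lobe
#' widths (~25-40 Å) put structure at the resolutions the matching is
#' sensitive to; the lack of symmetry makes the orientation search
#' informative. Deterministic for a given seed. This is a synthetic
#' stand-in for an experimental reference map such as a ribosome
#' reconstruction.
#'
#' @param box_size cubic box edge in voxels.
#' @param voxel_size voxel size in angstrom.
#' @param diameter nominal particle diameter in angstrom.
#' @param n_lobes number of Gaussian lobes.
#' @param seed RNG seed.
#' @return [density_volume].
#' @export
synthetic_template <- function(box_size = 32, voxel_size = 13.8, diameter = 300,
                               n_lobes = 8, seed = 1) {
  r_vox <- (diameter / 2) / voxel_size
  c0 <- box_size %/% 2
  ax <- (0:(box_size - 1)) - c0
  with_seed(seed, {
    # lobe centers inside 0.6 * radius, widths 25-40 A
    centers <- matrix(runif(3 * n_lobes, -0.6 * r_vox, 0.6 * r_vox), ncol = 3)
    sig <- runif(n_lobes, 25, 40) / voxel_size
    amp <- runif(n_lobes, 0.5, 1)
    vol <- array(0, c(box_size, box_size, box_size))
    gx <- rep(ax, times = box_size^2)
    gy <- rep(rep(ax, each = box_size), times = box_size)
    gz <- rep(ax, each = box_size^2)
    for (l in seq_len(n_lobes)) {
      d2 <- (gx - centers[l, 1])^2 + (gy - centers[l, 2])^2 + (gz - centers[l, 3])^2
      vol <- vol + amp[l] * exp(-d2 / (2 * sig[l]^2))
    }
    # soft window to zero at the nominal radius
    dist <- sqrt(gx^2 + gy^2 + gz^2)
    t <- (r_vox - dist) / 2
    win <- ifelse(t >= 1, 1, ifelse(t <= 0, 0, 0.5 - 0.5 * cos(pi * t)))
    density_volume(array(vol * win, c(box_size, box_size, box_size)), voxel_size)
  })
}

#' Generate a phantom tomogram with planted particles
#'
#' Plants `n_particles` copies of the template at seeded random positions
#' (pairwise separation at least `min_separation`, at least half a
#' template box from the volume faces) and uniformly random orientations
#' (random unit quaternions), degrades the summed volume with a binary
#' missing-wedge filter in Fourier space, and adds white Gaussian noise
#' calibrated so that `var(wedge-filtered signal) / var(noise) = snr`.
#' The defaults reflect the regime the package is validated in: a 128^3
#' tomogram at the template's voxel size with 25 ribosome-scale particles
#' at SNR 0.5 under a 39 degree missing wedge.
#'
#' @param template cubic [density_volume] to plant.
#' @param box length-3 phantom dimensions in voxels.
#' @param n_particles number of planted particles.
#' @param min_separation minimum pairwise center distance in angstrom.
#' @param snr signal-variance / noise-variance ratio (`Inf` = no noise).
#' @param wedge length-2 missing-wedge angles in degrees (`c(0, 0)` =
#'   full sampling).
#' @param seed RNG seed; the same seed reproduces the phantom bit for
#'   bit.
#' @param max_tries placement attempts per particle before giving up.
#' @return list with `tomogram` ([density_volume]), `truth`
#'   ([particle_list] of exact positions/orientations), `signal` (the
#'   noise-free wedge-filtered volume) and `noise_sd`.
#' @export
generate_phantom <- function(template, box = c(128, 128, 128), n_particles = 25,
                             min_separation = 350, snr = 0.5, wedge = c(39, 39),
                             seed = 1, max_tries = 10000) {
  stopifnot(is_density_volume(template))
  L <- dim(template)[1]
  if (length(unique(dim(template))) != 1L)
    stop("template must be cubic", call. = FALSE)
  if (any(L > box)) stop("template box exceeds the phantom box", call. = FALSE)
  vs <- template$voxel_size
  min_sep_vox <- min_separation / vs
  c0 <- L %/% 2
  lo <- c0
  hi <- box - L + c0  # valid-region bounds, 0-based

  with_seed(seed, {
    pos <- matrix(NA_real_, n_particles, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_particles) {
      tries <- tries + 1L
      if (tries > max_tries * n_particles)
        stop("could not place ", n_particles, " particles; reduce the count ",
             "or the minimum separation", call. = FALSE)
      cand <- vapply(1:3, function(a) round(runif(1, lo, hi[a])), numeric(1))
      if (placed > 0) {
        d <- sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))
        if (any(d < min_sep_vox)) next
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
    }

    q <- random_quaternions(n_particles)
    ang <- t(vapply(seq_len(n_particles), function(i) {
      matrix_to_euler(quaternion_to_matrix(q[, i]))
    }, numeric(3)))

    sig <- array(0, box)
    for (i in seq_len(n_particles)) {
      R <- euler_to_matrix(ang[i, 1], ang[i, 2], ang[i, 3])
      rt <- .cpp_rotate(as.double(template$data), as.integer(dim(template)),
                        as.double(R), 1L)
      ix <- (pos[i, 1] - c0 + 1):(pos[i, 1] - c0 + L)
      iy <- (pos[i, 2] - c0 + 1):(pos[i, 2] - c0 + L)
      iz <- (pos[i, 3] - c0 + 1):(pos[i, 3] - c0 + L)
      sig[ix, iy, iz] <- sig[ix, iy, iz] + rt
    }

    if (any(wedge > 0)) {
      wm <- build_wedge_mask(box, wedge)$data
      sig <- Re(fft3(fft3(sig) * as.vector(wm), inverse = TRUE))
      dim(sig) <- box
    }

    noise_sd <- 0
    tomo <- sig
    if (is.finite(snr)) {
      noise_sd <- sqrt(var(as.vector(sig)) / snr)
      tomo <- sig + array(rnorm(prod(box), 0, noise_sd), box)
    }

    truth <- particle_list(tomogram = "phantom",
                           x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           phi = ang[, 1], theta = ang[, 2], psi = ang[, 3],
                           score = NA_real_, voxel_size = vs,
                           tomogram_dims = box)
    list(tomogram = density_volume(tomo, vs), truth = truth,
         signal = density_volume(sig, vs), noise_sd = noise_sd)
  })
}
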