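#' Principal-axis alignment of a point cloud to the xy-plane
#'
#' Centers the coordinates and rotates them onto their principal axes so
#' that the direction of least variation ends up along z (the fitted
#' plane lies in xy). The returned rotation is always proper
#' (determinant +1, never a reflection).
#'
#' @param coordinates n x 3 matrix or data frame with columns `x`, `y`,
#'   `z` (>= 3 non-collinear points).
#' @return list with `coordinates` (centered, rotated tibble) and
#'   `rotation` (3x3 matrix mapping centered input columns onto the
#'   principal frame: `aligned = rotation %*% centered`).
#' @export
plane_align <- function(coordinates) {
  if (is.data.frame(coordinates))
    coordinates <- as.matrix(coordinates[, c("x", "y", "z")])
  if (nrow(coordinates) < 3)
    stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(coordinates)
  xc <- sweep(coordinates, 2, ctr)
  sv <- svd(xc)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point configuration", call. = FALSE)
  v <- sv$v  # columns ordered by decreasing variance
  if (det(v) < 0) v[, 3] <- -v[, 3]
  aligned <- xc %*% v
  colnames(aligned) <- c("x", "y", "z")
  list(coordinates = tibble::as_tibble(aligned), rotation = t(v))
}

#' Neighbor-density map in the particle reference frame
#'
#' For each particle, the vectors to its `n_neighbors` nearest neighbors
#' (excluding any closer than `exclusion_radius`) are rotated by the
#' inverse of the particle's orientation, so that neighbors accumulate
#' in the coordinate system of the aligned reference. The vectors are
#' binned on a 3D histogram of `hist_voxel`-sized voxels centered on the
#' reference particle and normalized by the number of analyzed
#' neighbors, giving the probability of finding a neighbor in each
#' voxel. Each unordered pair contributes once per member. With
#' `plane_align = TRUE` the accumulated vectors are first rotated so the
#' direction of least variation (e.g. the membrane normal) lies along z.
#'
#' @param particles [particle_list] with valid orientations.
#' @param voxel_size tomogram voxel size in angstrom (defaults to the
#'   particle list's own).
#' @param n_neighbors neighbors per reference particle.
#' @param exclusion_radius minimum neighbor distance in angstrom.
#' @param hist_voxel histogram voxel edge in angstrom.
#' @param extent histogram half-extent per axis in angstrom; vectors
#'   beyond it are dropped from the normalization.
#' @param plane_align align the fitted plane of the accumulated vectors
#'   with the xy-plane before binning.
#' @return object of class `neighbor_density` holding the normalized 3D
#'   `histogram` (probabilities summing to 1 when any neighbor was
#'   counted) and the analysis parameters.
#' @export
neighbor_density <- function(particles, voxel_size = NULL, n_neighbors = 4,
                             exclusion_radius = 100, hist_voxel = 20,
                             extent = 1000, plane_align = FALSE) {
  vs <- particle_voxel_size(particles, voxel_size)
  half <- floor(extent / hist_voxel)
  nbin <- 2L * half + 1L
  hist3 <- array(0, c(nbin, nbin, nbin))
  n <- nrow(particles)
  if (n >= 2) {
    pos <- as.matrix(particles[, c("x", "y", "z")]) * vs
    vecs <- vector("list", n)
    for (i in seq_len(n)) {
      d <- sweep(pos, 2, pos[i, ])
      dist <- sqrt(rowSums(d^2))
      sel <- which(dist >= exclusion_radius & seq_len(n) != i)
      if (!length(sel)) next
      sel <- sel[order(dist[sel])][seq_len(min(n_neighbors, length(sel)))]
      ri <- euler_to_matrix(particles$phi[i], particles$theta[i],
                            particles$psi[i])
      # neighbor vectors in the particle (template) frame
      vecs[[i]] <- t(t(ri) %*% t(d[sel, , drop = FALSE]))
    }
    acc <- do.call(rbind, vecs)
    if (!is.null(acc) && nrow(acc)) {
      if (plane_align && nrow(acc) >= 3) {
        colnames(acc) <- c("x", "y", "z")
        # rotate about the reference particle (origin), do not re-center
        acc <- t(plane_align(acc)$rotation %*% t(acc))
      }
      idx <- round(acc / hist_voxel)
      keep <- rowSums(abs(idx) <= half) == 3
      idx <- idx[keep, , drop = FALSE]
      if (nrow(idx)) {
        tab <- idx + half + 1
        for (r in seq_len(nrow(tab)))
          hist3[tab[r, 1], tab[r, 2], tab[r, 3]] <-
            hist3[tab[r, 1], tab[r, 2], tab[r, 3]] + 1
        hist3 <- hist3 / nrow(idx)
      }
    }
  }
  structure(list(histogram = hist3, hist_voxel = hist_voxel,
                 n_neighbors = n_neighbors,
                 exclusion_radius = exclusion_radius, extent = extent,
                 plane_aligned = isTRUE(plane_align)),
            class = "neighbor_density")
}

#' @export
print.neighbor_density <- function(x, ...) {
  cat(sprintf(
    "<neighbor_density> %d^3 voxels of (%g Å)^3, mass %.3f\n",
    dim(x$histogram)[1], x$hist_voxel, sum(x$histogram)))
  invisible(x)
}

#' Score-versus-depth profile of a particle layer
#'
#' Rotates the particle coordinates onto their principal axes (the
#' direction of least variation, e.g. the ice-layer normal, goes to z),
#' subtracts the median z so the layer center sits at z = 0, and returns
#' one (z, score) pair per particle. Depressed scores toward large |z|
#' indicate surface damage, e.g. from FIB milling.
#'
#' @param particles [particle_list] (>= 3 particles) with scores.
#' @param voxel_size tomogram voxel size in angstrom (defaults to the
#'   particle list's own).
#' @return tibble with `z` (angstrom, median-centered) and `score`; row
#'   count equals the particle count.
#' @export
lamella_profile <- function(particles, voxel_size = NULL) {
  vs <- particle_voxel_size(particles, voxel_size)
  if (nrow(particles) < 3) stop("need at least 3 particles", call. = FALSE)
  pos <- as.matrix(particles[, c("x", "y", "z")]) * vs
  colnames(pos) <- c("x", "y", "z")
  al <- plane_align(pos)
  z <- al$coordinates$z
  tibble::tibble(z = z - median(z), score = particles$score)
}
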