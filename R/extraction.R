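#' Extract ranked particle candidates from score volumes
#'
#' Iterative peak extraction: repeatedly take the global maximum of the
#' LCCmax volume within the valid region, record its position, score and
#' best-matching orientation, then invalidate a spherical region of the
#' given radius around it so nearby voxels cannot be picked again. Stops
#' early when only invalidated voxels remain. Ties in score break by
#' lexicographic (z, y, x) voxel order. Returned scores are exactly the
#' pre-masking LCCmax values; no sub-voxel interpolation is applied.
#'
#' @param scores `score_volumes` from [run_match()] or
#'   [split_and_merge()].
#' @param orientations the orientation set used for the search (row i+1
#'   is angle index i).
#' @param n maximum number of candidates (>= 1).
#' @param radius masking radius in voxels (>= 1).
#' @param tomogram_id id recorded on each candidate.
#' @return [particle_list] tibble ordered by decreasing score.
#' @export
extract_candidates <- function(scores, orientations, n, radius,
                               tomogram_id = "tomogram") {
  stopifnot(inherits(scores, "score_volumes"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(radius) || radius < 1)
    stop("`radius` must be >= 1 voxel", call. = FALSE)
  arr <- scores$lcc_max$data
  ang <- scores$angle_index
  d <- dim(arr)

  # relative offsets of the spherical suppression region
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, , drop = FALSE]

  out <- vector("list", n)
  found <- 0L
  for (i in seq_len(n)) {
    j <- which.max(arr)
    val <- arr[j]
    if (val <= -1 + 1e-12) break  # only masked/invalid voxels left
    # 0-based voxel coordinates from the linear index
    j0 <- j - 1L
    x <- j0 %% d[1]
    y <- (j0 %/% d[1]) %% d[2]
    z <- j0 %/% (d[1] * d[2])
    ai <- ang[j]
    ors <- orientations[ai + 1L, ]
    found <- found + 1L
    out[[found]] <- tibble::tibble(
      tomogram = tomogram_id, x = as.numeric(x), y = as.numeric(y),
      z = as.numeric(z), phi = ors$phi, theta = ors$theta, psi = ors$psi,
      score = val, angle_index = ai)
    # invalidate the sphere (clipped at the volume bounds)
    px <- x + off$dx
    py <- y + off$dy
    pz <- z + off$dz
    ok <- px >= 0 & px < d[1] & py >= 0 & py < d[2] & pz >= 0 & pz < d[3]
    arr[cbind(px[ok] + 1L, py[ok] + 1L, pz[ok] + 1L)] <- -1
  }
  df <- if (found) dplyr::bind_rows(out[seq_len(found)]) else
    tibble::tibble(tomogram = character(), x = numeric(), y = numeric(),
                   z = numeric(), phi = numeric(), theta = numeric(),
                   psi = numeric(), score = numeric(), angle_index = integer())
  pl <- as_particle_list(df[c("tomogram", "x", "y", "z", "phi", "theta",
                              "psi", "score")],
                         voxel_size = scores$lcc_max$voxel_size,
                         tomogram_dims = d)
  pl$angle_index <- df$angle_index
  pl
}
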