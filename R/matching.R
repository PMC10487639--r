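#' Rotate a cubic volume
#'
#' Active rotation about the box center (voxel `floor(n/2)`, 0-based).
#' The default interpolation is prefiltered cubic b-splines; voxels
#' mapped from outside the box are set to 0.
#'
#' @param v cubic [density_volume] or 3D array.
#' @param angles Euler triplet in degrees (ZXZ anticlockwise): numeric
#'   length 3 or a one-row data frame with `phi`, `theta`, `psi`.
#' @param rotation alternatively, a 3x3 rotation matrix (overrides
#'   `angles`).
#' @param interpolation `"cubic_bspline"` (default) or `"linear"`.
#' @return rotated volume, same class as the input.
#' @export
rotate_volume <- function(v, angles = NULL, rotation = NULL,
                          interpolation = c("cubic_bspline", "linear")) {
  interpolation <- match.arg(interpolation)
  arr <- as_volume_data(v)
  d <- dim(arr)
  if (length(unique(d)) != 1L) stop("volume must be cubic", call. = FALSE)
  if (is.null(rotation)) {
    if (is.null(angles)) stop("supply `angles` or `rotation`", call. = FALSE)
    a <- as_euler_df(angles)
    rotation <- euler_to_matrix(a$phi[1], a$theta[1], a$psi[1])
  }
  out <- .cpp_rotate(as.double(arr), as.integer(d), as.double(rotation),
                     if (interpolation == "cubic_bspline") 1L else 0L)
  if (is_density_volume(v)) density_volume(out, v$voxel_size) else out
}

#' Local standard deviation under a mask
#'
#' At each position x, the standard deviation of the volume over the mask
#' footprint centered there (mask center voxel `floor(L/2)`), computed by
#' FFT cross-correlation: `sqrt(mean(v^2 under M) - mean(v under M)^2)`,
#' clamped at 0. This is the denominator term of the local correlation.
#'
#' @param v [density_volume] or array (the search volume).
#' @param mask [density_volume] or array with values in `[0, 1]`; must
#'   not be all zero and must fit inside `v`.
#' @return [density_volume] of local standard deviations (same shape as
#'   `v`; positions near the border wrap around, as in the matching
#'   engine).
#' @export
local_std <- function(v, mask) {
  va <- as_volume_data(v)
  ma <- as_volume_data(mask)
  if (any(dim(ma) > dim(va))) stop("mask larger than volume", call. = FALSE)
  if (sum(ma) <= 0) stop("mask sums to zero", call. = FALSE)
  res <- .cpp_local_std(as.double(va), as.integer(dim(va)),
                        as.double(ma), as.integer(dim(ma)))
  vs <- if (is_density_volume(v)) v$voxel_size else 1
  density_volume(res$sd, vs)
}

resolve_wedge <- function(wedge, dims) {
  if (is.null(wedge)) return(NULL)
  if (is_density_volume(wedge)) {
    stopifnot(all(dim(wedge) == dims))
    return(as.double(wedge$data))
  }
  if (is.numeric(wedge) && length(wedge) == 2L)
    return(as.double(build_wedge_mask(dims, wedge)$data))
  stop("`wedge` must be NULL, length-2 angles, or a mask volume", call. = FALSE)
}

#' Local correlation for a single (pre-rotated) orientation
#'
#' The masked, locally normalized cross-correlation of a template against
#' a search volume, evaluated for all positions at once in Fourier space:
#' the rotated template is weighted by the missing-wedge mask, mean-
#' subtracted under the mask, normalized by its own standard deviation
#' and the local standard deviation of the volume, and divided by the
#' mask weight P. A perfect copy of the (wedge-filtered) template scores
#' 1 at its position; positions with local standard deviation below the
#' numerical floor score 0; the wrap-around margin is set to -1.
#'
#' @param v [density_volume] search volume.
#' @param template cubic [density_volume], already rotated to the target
#'   orientation.
#' @param mask matching mask, same box as the template.
#' @param wedge `NULL`, length-2 wedge angles in degrees, or a Fourier
#'   mask volume of the template box.
#' @return [density_volume] of scores in `[-1, 1]` (−1 marks the invalid
#'   margin).
#' @export
lcc_single_orientation <- function(v, template, mask, wedge = NULL) {
  va <- as_volume_data(v)
  ta <- as_volume_data(template)
  ma <- as_volume_data(mask)
  stopifnot(all(dim(ta) == dim(ma)))
  ident <- matrix(as.double(diag(3)), 9, 1)
  res <- .cpp_run_match(as.double(va), as.integer(dim(va)), as.double(ta),
                        as.double(ma), as.integer(dim(ta)),
                        resolve_wedge(wedge, dim(ta)), ident,
                        spherical = TRUE, interp = 1L,
                        std_floor_rel = 1e-8, verbose_every = 0L)
  vs <- if (is_density_volume(v)) v$voxel_size else 1
  density_volume(res$scores, vs)
}

#' Template-matching job
#'
#' Bundles everything one search needs: tomogram, template, mask,
#' missing-wedge specification, orientation set, subvolume split counts
#' and the spherical-mask shortcut flag (when the mask is spherical it
#' need not be rotated, and the expensive local standard deviation is
#' computed once and reused for every orientation).
#'
#' @param tomogram [density_volume].
#' @param template cubic [density_volume]; box must fit in the tomogram.
#' @param mask mask volume, same box as the template.
#' @param orientations an `orientation_set` tibble (see
#'   [generate_orientation_set()]).
#' @param wedge `NULL`, length-2 wedge angles in degrees, or a template-
#'   box Fourier mask.
#' @param split length-3 subvolume counts (nx, ny, nz) for
#'   [split_and_merge()].
#' @param spherical_mask logical; reuse the mask and local sd across
#'   orientations.
#' @param interpolation rotation interpolation for the template.
#' @return list of class `match_job`.
#' @export
match_job <- function(tomogram, template, mask, orientations, wedge = NULL,
                      split = c(1, 1, 1), spherical_mask = TRUE,
                      interpolation = c("cubic_bspline", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_density_volume(tomogram), is_density_volume(template))
  dt <- dim(template)
  if (length(unique(dt)) != 1L) stop("template box must be cubic", call. = FALSE)
  if (!all(dim(as_volume_data(mask)) == dt))
    stop("template and mask must share one box size", call. = FALSE)
  if (any(dt > dim(tomogram)))
    stop("template box exceeds the tomogram", call. = FALSE)
  if (!nrow(orientations)) stop("empty orientation set", call. = FALSE)
  structure(list(tomogram = tomogram, template = template, mask = mask,
                 orientations = orientations, wedge = wedge,
                 split = as.integer(split), spherical_mask = spherical_mask,
                 interpolation = interpolation),
            class = "match_job")
}

#' Run the orientation search
#'
#' For each orientation in order, rotates the template (and, unless the
#' spherical-mask flag is set, the mask), applies the missing-wedge
#' weighting in the tomogram frame, computes the local correlation at
#' every position by FFT, and keeps the per-voxel running maximum
#' (LCCmax) together with the 0-based index of the orientation achieving
#' it. Ties go to the lowest orientation index. Scores within half a
#' template box of the volume faces are invalid (wrap-around) and set to
#' -1.
#'
#' @param job a [match_job].
#' @param verbose_every print progress every this many orientations
#'   (0 = silent).
#' @return object of class `score_volumes`: `lcc_max` and `angle_index`
#'   volumes, the valid margin, and the orientation count.
#' @export
run_match <- function(job, verbose_every = 0) {
  stopifnot(inherits(job, "match_job"))
  ors <- job$orientations
  rot <- euler_zxz_matrices(ors$phi, ors$theta, ors$psi)
  dt <- dim(job$template)
  res <- .cpp_run_match(as.double(job$tomogram$data), as.integer(dim(job$tomogram)),
                        as.double(job$template$data),
                        as.double(as_volume_data(job$mask)), as.integer(dt),
                        resolve_wedge(job$wedge, dt), rot,
                        spherical = isTRUE(job$spherical_mask),
                        interp = if (job$interpolation == "cubic_bspline") 1L else 0L,
                        std_floor_rel = 1e-8,
                        verbose_every = as.integer(verbose_every))
  new_score_volumes(res$scores, res$angle_index, job$tomogram$voxel_size,
                    c(res$margin_lo, res$margin_hi), nrow(ors))
}

new_score_volumes <- function(scores, angle_index, voxel_size, margin, n_orient) {
  structure(list(lcc_max = density_volume(scores, voxel_size),
                 angle_index = angle_index,
                 valid_margin = as.integer(margin),
                 n_orientations = n_orient),
            class = "score_volumes")
}

#' @export
print.score_volumes <- function(x, ...) {
  d <- dim(x$lcc_max$data)
  cat(sprintf("<score_volumes> %d x %d x %d, %d orientations, margin %d/%d\n",
              d[1], d[2], d[3], x$n_orientations,
              x$valid_margin[1], x$valid_margin[2]))
  invisible(x)
}

#' Split the search over subvolumes and/or angle partitions
#'
#' Subvolumes overlap by one full template box on shared faces; each
#' piece is matched independently, cropped back to its interior, and the
#' pieces are concatenated. The angular search can additionally be
#' partitioned into chunks whose results merge by pointwise maximum
#' (lowest orientation index wins ties), which reproduces the serial
#' result exactly. The assembled volume equals [run_match()] on the
#' unsplit volume everywhere in the valid region.
#'
#' @param job a [match_job] whose `split` gives the subvolume counts.
#' @param angle_chunks number of partitions of the orientation set.
#' @return `score_volumes`, as from [run_match()].
#' @export
split_and_merge <- function(job, angle_chunks = 1) {
  stopifnot(inherits(job, "match_job"))
  dv <- dim(job$tomogram)
  L <- dim(job$template)[1]
  sp <- job$split
  stopifnot(length(sp) == 3, all(sp >= 1))
  ors <- job$orientations
  n_or <- nrow(ors)
  chunks <- split(seq_len(n_or), ceiling(seq_len(n_or) / ceiling(n_or / angle_chunks)))

  axis_ranges <- function(n, k) {
    b <- floor(seq(0, n, length.out = k + 1))
    lapply(seq_len(k), function(i) c(b[i] + 1, b[i + 1]))  # 1-based inclusive
  }
  rx <- axis_ranges(dv[1], sp[1])
  ry <- axis_ranges(dv[2], sp[2])
  rz <- axis_ranges(dv[3], sp[3])

  scores <- array(-1, dv)
  angles <- array(0L, dv)

  for (iz in seq_along(rz)) for (iy in seq_along(ry)) for (ix in seq_along(rx)) {
    intr <- list(rx[[ix]], ry[[iy]], rz[[iz]])
    ext <- lapply(1:3, function(a) {
      lo <- max(1, intr[[a]][1] - L)
      hi <- min(dv[a], intr[[a]][2] + L)
      c(lo, hi)
    })
    sub_dims <- vapply(ext, function(e) e[2] - e[1] + 1, numeric(1))
    if (any(sub_dims < L))
      stop("subvolume smaller than the template box after overlap", call. = FALSE)
    sub <- job$tomogram$data[ext[[1]][1]:ext[[1]][2],
                             ext[[2]][1]:ext[[2]][2],
                             ext[[3]][1]:ext[[3]][2], drop = FALSE]
    best <- NULL
    bidx <- NULL
    for (ci in seq_along(chunks)) {
      ids <- chunks[[ci]]
      rot <- euler_zxz_matrices(ors$phi[ids], ors$theta[ids], ors$psi[ids])
      res <- .cpp_run_match(as.double(sub), as.integer(dim(sub)),
                            as.double(job$template$data),
                            as.double(as_volume_data(job$mask)),
                            as.integer(dim(job$template)),
                            resolve_wedge(job$wedge, dim(job$template)), rot,
                            spherical = isTRUE(job$spherical_mask),
                            interp = if (job$interpolation == "cubic_bspline") 1L else 0L,
                            std_floor_rel = 1e-8, verbose_every = 0L)
      s <- res$scores
      a <- res$angle_index + (ids[1] - 1L)  # chunk-local -> global indices
      if (is.null(best)) {
        best <- s
        bidx <- a
      } else {
        upd <- s > best
        best[upd] <- s[upd]
        bidx[upd] <- a[upd]
      }
    }
    # crop back to the interior
    ii <- lapply(1:3, function(a) (intr[[a]][1]:intr[[a]][2]) - ext[[a]][1] + 1)
    scores[intr[[1]][1]:intr[[1]][2], intr[[2]][1]:intr[[2]][2],
           intr[[3]][1]:intr[[3]][2]] <- best[ii[[1]], ii[[2]], ii[[3]]]
    angles[intr[[1]][1]:intr[[1]][2], intr[[2]][1]:intr[[2]][2],
           intr[[3]][1]:intr[[3]][2]] <- bidx[ii[[1]], ii[[2]], ii[[3]]]
  }

  c0 <- L %/% 2
  # global wrap-around margin
  mark <- function(arr, val) {
    arr[c(seq_len(c0), (dv[1] - (L - c0 - 1) + 1):dv[1]), , ] <- val
    arr[, c(seq_len(c0), (dv[2] - (L - c0 - 1) + 1):dv[2]), ] <- val
    arr[, , c(seq_len(c0), (dv[3] - (L - c0 - 1) + 1):dv[3])] <- val
    arr
  }
  scores <- mark(scores, -1)
  angles <- mark(angles, 0L)
  new_score_volumes(scores, angles, job$tomogram$voxel_size,
                    c(c0, L - c0 - 1), n_or)
}

#' LCCmax at chosen positions
#'
#' Evaluates the same score as [run_match()] but only at the given
#' voxels, which makes very large orientation sets affordable when the
#' full score volume is not needed (e.g. scoring known particle
#' positions). Requires the spherical-mask shortcut.
#'
#' @param job a [match_job] with `spherical_mask = TRUE`.
#' @param positions data frame with 0-based voxel columns `x`, `y`, `z`
#'   (must lie in the valid region).
#' @return tibble with `x`, `y`, `z`, `lcc_max` and 0-based
#'   `angle_index`.
#' @export
score_at_positions <- function(job, positions) {
  stopifnot(inherits(job, "match_job"), isTRUE(job$spherical_mask))
  pos <- as.matrix(positions[, c("x", "y", "z")])
  storage.mode(pos) <- "integer"
  ors <- job$orientations
  rot <- euler_zxz_matrices(ors$phi, ors$theta, ors$psi)
  dt <- dim(job$template)
  res <- .cpp_score_at_positions(
    as.double(job$tomogram$data), as.integer(dim(job$tomogram)),
    as.double(job$template$data), as.double(as_volume_data(job$mask)),
    as.integer(dt), resolve_wedge(job$wedge, dt), rot, pos,
    interp = if (job$interpolation == "cubic_bspline") 1L else 0L,
    std_floor_rel = 1e-8)
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 lcc_max = res$scores, angle_index = res$angle_index)
}
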