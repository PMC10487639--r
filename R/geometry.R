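#' Angular increment from the Crowther criterion
#'
#' The minimum rotational sampling needed to match a particle of diameter
#' `d` at a target resolution `r` is `delta_alpha = 1 / (r * d)` radians:
#' a point at radius d/2 then moves by about one Nyquist voxel under a
#' rotation by one increment.
#'
#' @param diameter particle diameter d in angstrom (> 0).
#' @param resolution target resolution r in 1/angstrom (> 0), e.g. `1/40`
#'   for a 40 Å target.
#' @return An object of class `angular_sampling` with elements `diameter`,
#'   `resolution`, `radians` and `degrees`.
#' @examples
#' crowther_increment(300, 1 / 40)  # 0.133 rad, 7.64 degrees
#' @export
crowther_increment <- function(diameter, resolution) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    stop("`diameter` must be a single positive number (angstrom)", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || !is.finite(resolution) ||
      resolution <= 0)
    stop("`resolution` must be a single positive number (1/angstrom)", call. = FALSE)
  rad <- 1 / (resolution * diameter)
  structure(list(diameter = diameter, resolution = resolution,
                 radians = rad, degrees = rad * 180 / pi),
            class = "angular_sampling")
}

#' @export
print.angular_sampling <- function(x, ...) {
  cat(sprintf("<angular_sampling> d = %g Å, r = %g 1/Å: %.4f rad (%.2f deg)\n",
              x$diameter, x$resolution, x$radians, x$degrees))
  invisible(x)
}

#' Quasi-uniform orientation set over SO(3)
#'
#' Deterministic cover of rotation space at a given angular increment:
#' the first two Euler angles come from a Fibonacci (spiral) lattice on
#' the sphere with point density matched to the increment, and the third
#' (in-plane) angle is sampled uniformly in `[0, 360)` at the increment.
#' Angles are ZXZ anticlockwise, in degrees. Row order is deterministic
#' and stable: row i is the orientation referenced by angle index i-1 in
#' score volumes.
#'
#' @param increment angular increment in degrees, in (0, 180].
#' @return A tibble of class `orientation_set` with columns `phi`,
#'   `theta`, `psi`, and attributes `increment`, `convention`,
#'   `provenance`.
#' @examples
#' nrow(generate_orientation_set(13))  # about 7000 orientations
#' @export
generate_orientation_set <- function(increment) {
  if (!is.numeric(increment) || length(increment) != 1L || !is.finite(increment) ||
      increment <= 0 || increment > 180)
    stop("`increment` must be in (0, 180] degrees", call. = FALSE)
  da <- increment * pi / 180
  n_sphere <- max(1L, as.integer(round(4 * pi / da^2)))
  n_psi <- max(1L, as.integer(round(360 / increment)))
  i <- seq_len(n_sphere) - 1
  z <- 1 - 2 * (i + 0.5) / n_sphere
  theta <- acos(pmin(1, pmax(-1, z))) * 180 / pi
  golden <- 180 * (3 - sqrt(5))  # golden angle, ~137.5078 degrees
  phi <- ((i * golden) + 90) %% 360
  psi <- (seq_len(n_psi) - 1) * (360 / n_psi)
  out <- tibble::tibble(
    phi = rep(phi, each = n_psi),
    theta = rep(theta, each = n_psi),
    psi = rep(psi, times = n_sphere)
  )
  new_orientation_set(out, increment, "generated")
}

new_orientation_set <- function(df, increment, provenance) {
  if (nrow(df) < 1L) stop("orientation set must be nonempty", call. = FALSE)
  structure(df,
            class = c("orientation_set", class(tibble::tibble())),
            increment = increment,
            convention = "zxz_anticlockwise",
            provenance = provenance)
}

#' Write / read an orientation set as plain text
#'
#' One `phi theta psi` triple per line (degrees, ZXZ anticlockwise) with a
#' single header line recording the increment.
#'
#' @param x orientation set (tibble with `phi`, `theta`, `psi`).
#' @param path file path.
#' @return `write_orientation_set` returns `x` invisibly;
#'   `read_orientation_set` returns an `orientation_set` tibble.
#' @export
write_orientation_set <- function(x, path) {
  inc <- attr(x, "increment")
  if (is.null(inc)) inc <- NA_real_
  header <- sprintf("# increment %.6f degrees, zxz_anticlockwise", inc)
  lines <- sprintf("%.8f %.8f %.8f", x$phi, x$theta, x$psi)
  writeLines(c(header, lines), path)
  invisible(x)
}

#' @rdname write_orientation_set
#' @export
read_orientation_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("missing orientation-set header line", call. = FALSE)
  inc <- suppressWarnings(as.numeric(strsplit(trimws(sub("^#", "", lines[1])),
                                              "\\s+")[[1]][2]))
  vals <- utils::read.table(text = lines[-1], col.names = c("phi", "theta", "psi"))
  new_orientation_set(tibble::as_tibble(vals), inc, "loaded")
}

#' Euler angles to rotation matrix
#'
#' Active rotation matrix for a Euler triplet under one of two
#' conventions. `zxz_anticlockwise` (the native convention) composes
#' `Rz(phi) %*% Rx(theta) %*% Rz(psi)` with anticlockwise-positive angles
#' viewed from the positive axis; `zyz_clockwise` (the RELION-style
#' convention) composes `Rz(-rot) %*% Ry(-tilt) %*% Rz(-psi)`.
#'
#' @param phi,theta,psi Euler angles in degrees. For `zyz_clockwise`,
#'   these are rot, tilt, psi respectively.
#' @param convention `"zxz_anticlockwise"` or `"zyz_clockwise"`.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_to_matrix(0, 0, 0)  # identity
#' @export
euler_to_matrix <- function(phi, theta, psi,
                            convention = c("zxz_anticlockwise", "zyz_clockwise")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi))
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  if (convention == "zxz_anticlockwise") {
    rz(phi) %*% rx(theta) %*% rz(psi)
  } else {
    rz(-phi) %*% ry(-theta) %*% rz(-psi)
  }
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_matrix()]. Near gimbal lock (middle angle 0 or
#' 180 within ~1e-8 degrees) the in-plane rotation is placed entirely on
#' the third angle with the first angle set to 0, making the output
#' deterministic.
#'
#' @param R 3x3 rotation matrix.
#' @inheritParams euler_to_matrix
#' @return Named numeric vector of the three angles in degrees; the
#'   middle angle lies in `[0, 180]`.
#' @export
matrix_to_euler <- function(R, convention = c("zxz_anticlockwise", "zyz_clockwise")) {
  convention <- match.arg(convention)
  deg <- function(x) x * 180 / pi
  tol <- 1 - 1e-12
  if (convention == "zxz_anticlockwise") {
    ct <- clamp1(R[3, 3])
    if (ct >= tol) {                    # theta ~ 0: pure z-rotation
      ang <- deg(atan2(R[2, 1], R[1, 1]))
      out <- c(phi = 0, theta = 0, psi = ang %% 360)
    } else if (ct <= -tol) {            # theta ~ 180
      ang <- deg(atan2(-R[2, 1], R[1, 1]))
      out <- c(phi = 0, theta = 180, psi = ang %% 360)
    } else {
      theta <- deg(acos(ct))
      phi <- deg(atan2(R[1, 3], -R[2, 3]))
      psi <- deg(atan2(R[3, 1], R[3, 2]))
      out <- c(phi = phi %% 360, theta = theta, psi = psi %% 360)
    }
    out
  } else {
    # decompose R = Rz(a) Ry(b) Rz(g) with b in [-180, 0], return -(a,b,g)
    cb <- clamp1(R[3, 3])
    if (cb >= tol) {                    # tilt ~ 0
      g <- deg(atan2(R[2, 1], R[1, 1]))
      c(phi = 0, theta = 0, psi = (-g) %% 360)
    } else if (cb <= -tol) {            # tilt ~ 180
      g <- deg(atan2(R[2, 1], -R[1, 1]))
      c(phi = 0, theta = 180, psi = (-g) %% 360)
    } else {
      b <- -deg(acos(cb))
      a <- deg(atan2(-R[2, 3], -R[1, 3]))
      g <- deg(atan2(-R[3, 2], R[3, 1]))
      c(phi = (-a) %% 360, theta = -b, psi = (-g) %% 360)
    }
  }
}

#' Convert native ZXZ-anticlockwise angles to RELION ZYZ-clockwise angles
#'
#' The native triplets are turned into rotation matrices, decomposed as
#' ZYZ Euler angles and negated, which yields the clockwise convention
#' used by RELION (and XMIPP/SPIDER/FREALIGN). The rotation described is
#' identical; only the parametrization changes.
#'
#' @param angles data frame with columns `phi`, `theta`, `psi` in degrees
#'   (ZXZ anticlockwise), or a numeric length-3 vector.
#' @return A tibble with columns `rot`, `tilt`, `psi` (degrees,
#'   ZYZ clockwise); `tilt` lies in `[0, 180]`.
#' @examples
#' pytom_to_relion_euler(c(0, 0, 0))
#' @export
pytom_to_relion_euler <- function(angles) {
  angles <- as_euler_df(angles)
  out <- purrr::pmap(angles, function(phi, theta, psi) {
    R <- euler_to_matrix(phi, theta, psi, "zxz_anticlockwise")
    e <- matrix_to_euler(R, "zyz_clockwise")
    tibble::tibble(rot = e[["phi"]], tilt = e[["theta"]], psi = e[["psi"]])
  })
  dplyr::bind_rows(out)
}

#' @rdname pytom_to_relion_euler
#' @param angles for the reverse direction, a data frame with columns
#'   `rot`, `tilt`, `psi` (degrees, ZYZ clockwise) or a length-3 vector.
#' @export
relion_to_pytom_euler <- function(angles) {
  if (is.numeric(angles) && length(angles) == 3L)
    angles <- tibble::tibble(rot = angles[1], tilt = angles[2], psi = angles[3])
  stopifnot(all(c("rot", "tilt", "psi") %in% names(angles)))
  out <- purrr::pmap(angles[c("rot", "tilt", "psi")], function(rot, tilt, psi) {
    R <- euler_to_matrix(rot, tilt, psi, "zyz_clockwise")
    e <- matrix_to_euler(R, "zxz_anticlockwise")
    tibble::tibble(phi = e[["phi"]], theta = e[["theta"]], psi = e[["psi"]])
  })
  dplyr::bind_rows(out)
}

as_euler_df <- function(angles) {
  if (is.numeric(angles) && length(angles) == 3L)
    angles <- tibble::tibble(phi = angles[1], theta = angles[2], psi = angles[3])
  if (!all(c("phi", "theta", "psi") %in% names(angles)))
    stop("need columns `phi`, `theta`, `psi`", call. = FALSE)
  angles[c("phi", "theta", "psi")]
}

# vectorized closed-form ZXZ matrices, packed column-major as a 9 x n
# matrix for the C++ scoring loop
euler_zxz_matrices <- function(phi, theta, psi) {
  p <- phi * pi / 180
  t <- theta * pi / 180
  s <- psi * pi / 180
  cp <- cos(p); sp <- sin(p); ct <- cos(t); st <- sin(t); cs <- cos(s); ss <- sin(s)
  rbind(
    cp * cs - sp * ct * ss,   # R11
    sp * cs + cp * ct * ss,   # R21
    st * ss,                  # R31
    -cp * ss - sp * ct * cs,  # R12
    -sp * ss + cp * ct * cs,  # R22
    st * cs,                  # R32
    sp * st,                  # R13
    -cp * st,                 # R23
    ct                        # R33
  )
}

#' Quaternions and the geodesic metric on SO(3)
#'
#' `euler_to_quaternion` maps ZXZ-anticlockwise triplets (rows of a data
#' frame, degrees) to unit quaternions (w, x, y, z rows); the sign of w
#' is fixed non-negative. `rotation_geodesic` returns the bi-invariant
#' geodesic distance in degrees between quaternion columns,
#' `2 * acos(|q1 . q2|)`.
#'
#' @param angles data frame with `phi`, `theta`, `psi` in degrees.
#' @return `euler_to_quaternion`: a 4 x n matrix of unit quaternions.
#' @export
euler_to_quaternion <- function(angles) {
  angles <- as_euler_df(angles)
  # ZXZ factorization: q = qz(phi) * qx(theta) * qz(psi)
  hp <- angles$phi * pi / 360
  ht <- angles$theta * pi / 360
  hs <- angles$psi * pi / 360
  # qz(a) = (cos a/2, 0, 0, sin a/2); qx(a) = (cos a/2, sin a/2, 0, 0)
  w <- cos(ht) * cos(hp + hs)
  x <- sin(ht) * cos(hp - hs)
  y <- sin(ht) * sin(hp - hs)
  z <- cos(ht) * sin(hp + hs)
  q <- rbind(w, x, y, z)
  flip <- q[1, ] < 0
  q[, flip] <- -q[, flip]
  q
}

#' @rdname euler_to_quaternion
#' @param q1,q2 4 x n quaternion matrices (columns are quaternions).
#' @return `rotation_geodesic`: matrix of pairwise distances in degrees
#'   (rows index `q1` columns, columns index `q2` columns).
#' @export
rotation_geodesic <- function(q1, q2) {
  d <- abs(crossprod(q1, q2))
  d[d > 1] <- 1  # guard acos against rounding
  2 * acos(d) * 180 / pi
}

# seeded uniform random rotations as a 4 x n quaternion matrix
random_quaternions <- function(n) {
  m <- matrix(rnorm(4 * n), nrow = 4)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  flip <- m[1, ] < 0
  m[, flip] <- -m[, flip]
  m
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}
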