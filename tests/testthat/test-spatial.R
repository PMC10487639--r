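test_that("plane alignment sends the thin direction to z and never
           reflects", {
  set.seed(1)
  # points in the z = 5 plane
  flat <- tibble::tibble(x = runif(50, -100, 100), y = runif(50, -100, 100),
                         z = 5)
  al <- plane_align(flat)
  expect_lt(var(al$coordinates$z) / sum(diag(var(as.matrix(flat)))), 1e-12)
  expect_equal(det(al$rotation), 1, tolerance = 1e-12)

  # tilted slab: the recovered normal is within 1 degree of truth
  slab <- cbind(runif(500, -200, 200), runif(500, -200, 200),
                rnorm(500, 0, 2))
  tilt <- euler_to_matrix(0, 15, 0)  # rotate the slab by a known 15 degrees
  pts <- slab %*% t(tilt)
  colnames(pts) <- c("x", "y", "z")
  al2 <- plane_align(pts)
  normal_est <- al2$rotation[3, ]  # least-variance direction in input frame
  normal_true <- tilt %*% c(0, 0, 1)
  ang <- acos(min(1, abs(sum(normal_est * normal_true)))) * 180 / pi
  expect_lt(ang, 1)

  # aligned input: re-alignment is near-identity on the variance structure
  al3 <- plane_align(al2$coordinates)
  expect_equal(abs(diag(al3$rotation)), c(1, 1, 1), tolerance = 1e-6)
  expect_error(plane_align(tibble::tibble(x = 1:5, y = 2 * (1:5), z = 3 * (1:5))),
               "collinear")
  expect_error(plane_align(flat[1:2, ]), "3 points")
})

test_that("two identity-orientation particles produce symmetric neighbor
           mass; close pairs are excluded", {
  pl <- particle_list(tomogram = "t", x = c(0, 300 / 13.8), y = c(0, 0),
                      z = c(0, 0), phi = 0, theta = 0, psi = 0,
                      score = 0.5, voxel_size = 13.8)
  nd <- neighbor_density(pl)
  expect_equal(sum(nd$histogram), 1)
  half <- (dim(nd$histogram)[1] - 1) / 2
  ctr <- half + 1
  expect_equal(nd$histogram[ctr + 15, ctr, ctr], 0.5)  # +300 A at 20 A voxels
  expect_equal(nd$histogram[ctr - 15, ctr, ctr], 0.5)
  # 80 A apart: inside the exclusion radius, histogram stays empty
  pl2 <- particle_list(tomogram = "t", x = c(0, 80 / 13.8), y = c(0, 0),
                       z = c(0, 0), phi = 0, theta = 0, psi = 0,
                       score = 0.5, voxel_size = 13.8)
  expect_equal(sum(neighbor_density(pl2)$histogram), 0)
  # single particle: empty density, not an error
  single <- particle_list(tomogram = "t", x = 1, y = 1, z = 1, phi = 0,
                          theta = 0, psi = 0, score = 0.1, voxel_size = 10)
  expect_equal(sum(neighbor_density(single)$histogram), 0)
  # missing voxel size is an error
  nosize <- particle_list(tomogram = "t", x = 1, y = 1, z = 1, phi = 0,
                          theta = 0, psi = 0, score = 0.1)
  expect_error(neighbor_density(nosize), "voxel size")
})

test_that("in-plane neighbors land in the central z-slab at their true
           radius after rotation into the particle frame", {
  set.seed(3)
  n_ref <- 60
  vs <- 10
  sep <- 250
  rows <- list()
  for (i in seq_len(n_ref)) {
    ctr <- c(i * 3000, 0, 0)  # clusters far apart so they never mix
    phi_i <- runif(1, 0, 360)  # random in-plane orientation about z
    ri <- euler_to_matrix(phi_i, 0, 0)
    partner <- ctr + as.numeric(ri %*% c(sep, 0, 0))
    rows[[i]] <- tibble::tibble(
      tomogram = "t", x = c(ctr[1], partner[1]) / vs,
      y = c(ctr[2], partner[2]) / vs, z = c(ctr[3], partner[3]) / vs,
      phi = c(phi_i, 0), theta = 0, psi = 0, score = 0.5)
  }
  pl <- as_particle_list(dplyr::bind_rows(rows), voxel_size = vs)
  nd <- neighbor_density(pl, n_neighbors = 1, exclusion_radius = 100,
                         hist_voxel = 20)
  h <- nd$histogram
  expect_equal(sum(h), 1)
  half <- (dim(h)[1] - 1) / 2
  ctr_i <- half + 1
  # in-plane geometry stays in the central z-slab
  expect_gt(sum(h[, , ctr_i]), 0.99)
  # all neighbor mass sits at the separation radius +/- one histogram voxel
  ax <- ((1:dim(h)[1]) - ctr_i) * 20
  rad <- sqrt(outer(ax^2, ax^2, "+"))
  xy <- apply(h, c(1, 2), sum)
  expect_gt(sum(xy[abs(rad - sep) <= 20 * sqrt(2)]), 0.99)
  # references see their partner along +x in their own frame
  expect_gte(sum(h[ctr_i + 12:13, ctr_i + (-1:1), ctr_i]), 0.5 - 1e-9)
})

test_that("neighbor densities are invariant to a global rigid-body motion", {
  set.seed(9)
  n <- 30
  pl <- particle_list(tomogram = "t",
                      x = runif(n, 0, 100), y = runif(n, 0, 100),
                      z = runif(n, 0, 100),
                      phi = runif(n, 0, 360), theta = runif(n, 0, 180),
                      psi = runif(n, 0, 360), score = 0.5, voxel_size = 10)
  nd1 <- neighbor_density(pl)
  # apply one rotation G to all positions and orientations
  g <- euler_to_matrix(25, 40, 60)
  pos <- as.matrix(pl[, c("x", "y", "z")]) %*% t(g)
  moved <- pl
  moved$x <- pos[, 1]; moved$y <- pos[, 2]; moved$z <- pos[, 3]
  for (i in seq_len(n)) {
    ri <- g %*% euler_to_matrix(pl$phi[i], pl$theta[i], pl$psi[i])
    e <- matrix_to_euler(ri)
    moved$phi[i] <- e[1]; moved$theta[i] <- e[2]; moved$psi[i] <- e[3]
  }
  nd2 <- neighbor_density(moved)
  # discretization can move mass by one voxel; compare smoothed masses
  expect_equal(sum(nd2$histogram), sum(nd1$histogram))
  expect_lt(mean(abs(nd1$histogram - nd2$histogram)), 1e-4)
})

test_that("lamella profiles are median-centered and reveal depth-dependent
           score loss", {
  set.seed(5)
  n <- 400
  vs <- 14.8
  # slab tilted by 12 degrees with scores decaying away from the center
  z0 <- runif(n, -1000, 1000)
  base <- cbind(runif(n, -3000, 3000), runif(n, -3000, 3000), z0)
  tilt <- euler_to_matrix(0, 12, 0)
  pts <- base %*% t(tilt)
  score <- 0.3 * exp(-(z0 / 700)^2) + rnorm(n, 0, 0.01)
  pl <- particle_list(tomogram = "t", x = pts[, 1] / vs, y = pts[, 2] / vs,
                      z = pts[, 3] / vs, phi = 0, theta = 0, psi = 0,
                      score = pmax(-1, pmin(1, score)), voxel_size = vs)
  prof <- lamella_profile(pl)
  expect_equal(nrow(prof), n)
  expect_equal(median(prof$z), 0)
  top <- prof$z[order(prof$score, decreasing = TRUE)][1:40]
  bottom <- prof$z[order(prof$score)][1:40]
  expect_lt(median(abs(top)), median(abs(bottom)))
})
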