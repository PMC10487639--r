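# Shared fixtures, built once per test run and memoized. All synthetic.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, fixture_env)) assign(name, force(expr), fixture_env)
  get(name, fixture_env)
}

# ribosome-scale synthetic template at the study voxel size
fx_template <- function() memo("template", synthetic_template(
  box_size = 32, voxel_size = 13.8, diameter = 300, seed = 1))

fx_mask <- function() memo("mask", build_spherical_mask(
  32, diameter = 350, voxel_size = 13.8, soft_edge_sigma = 1.5))

# small, quiet phantom for fast module tests
fx_small_phantom <- function() memo("small_phantom", generate_phantom(
  fx_template(), box = c(96, 96, 96), n_particles = 6, min_separation = 350,
  snr = 2, wedge = c(39, 39), seed = 7))

# the validation-scale phantom and its full 15-degree search (heavy; used
# by the acceptance tests, computed once)
fx_acceptance_run <- function() memo("acceptance_run", {
  tpl <- fx_template()
  ph <- generate_phantom(tpl, box = c(128, 128, 128), n_particles = 25,
                         min_separation = 350, snr = 0.5, wedge = c(39, 39),
                         seed = 1)
  ors <- generate_orientation_set(15)
  job <- match_job(ph$tomogram, tpl, fx_mask(), ors, wedge = c(39, 39))
  res <- run_match(job)
  cand <- extract_candidates(res, ors, n = 200, radius = 9,
                             tomogram_id = "phantom")
  list(phantom = ph, orientations = ors, job = job, scores = res,
       candidates = cand)
})

expect_rotation_matrix <- function(R, tol = 1e-10) {
  expect_equal(crossprod(R), diag(3), tolerance = tol, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = tol)
}

# distance of each row of `a` to the nearest row of `b` (voxel coords)
nearest_dist <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rep(1, nrow(bm))) +
    outer(rep(1, nrow(am)), rowSums(bm^2)) - 2 * am %*% t(bm)
  sqrt(pmax(apply(d2, 1, min), 0))
}
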