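test_that("volume rotation: identity, axis-aligned delta mapping, and
           intensity preservation", {
  set.seed(1)
  v <- array(rnorm(24^3), rep(24, 3))
  expect_lt(max(abs(rotate_volume(v, c(0, 0, 0)) - v)), 1e-6)

  # 90-degree z-rotation maps an off-center delta to the analytic voxel
  d <- array(0, rep(16, 3))
  d[12, 9, 9] <- 1  # 0-based (11, 8, 8); center c = (8, 8, 8)
  r <- rotate_volume(d, c(90, 0, 0))
  # R(90 about z) maps (3,0,0) -> (0,3,0), i.e. voxel (8,11,8)
  expect_equal(r[9, 12, 9], 1, tolerance = 1e-6)
  expect_lt(sum(abs(r)) - 1, 1e-4)

  # smooth blob: total intensity preserved within 1% under rotation
  ax <- (0:31) - 16
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  g <- array(exp(-d2 / 18), rep(32, 3))
  gr <- rotate_volume(g, c(33, 57, 121))
  expect_equal(sum(gr) / sum(g), 1, tolerance = 0.01)
  expect_error(rotate_volume(array(0, c(4, 5, 4)), c(0, 0, 0)), "cubic")
})

test_that("local_std equals the sliding-window computation and is
           shift/constant invariant", {
  set.seed(2)
  v <- array(rnorm(16^3), rep(16, 3))
  m <- build_spherical_mask(8, 6, 1, 1)$data
  ls <- local_std(v, m)$data
  P <- sum(m)
  c0 <- 4
  brute <- function(x, y, z) {  # 0-based position, circular like the FFT
    s1 <- 0; s2 <- 0
    for (k in 0:7) for (j in 0:7) for (i in 0:7) {
      vi <- v[(x + i - c0) %% 16 + 1, (y + j - c0) %% 16 + 1,
              (z + k - c0) %% 16 + 1]
      s1 <- s1 + m[i + 1, j + 1, k + 1] * vi
      s2 <- s2 + m[i + 1, j + 1, k + 1] * vi^2
    }
    sqrt(max(0, s2 / P - (s1 / P)^2))
  }
  pos <- matrix(c(8, 8, 8, 3, 12, 7, 0, 0, 0, 15, 2, 9, 5, 5, 14), ncol = 3,
                byrow = TRUE)
  for (r in seq_len(nrow(pos)))
    expect_lt(abs(ls[pos[r, 1] + 1, pos[r, 2] + 1, pos[r, 3] + 1] -
                    brute(pos[r, 1], pos[r, 2], pos[r, 3])), 1e-6)

  # constant volume -> zero everywhere; adding a constant changes nothing
  expect_true(all(local_std(array(3, rep(16, 3)), m)$data == 0))
  expect_equal(local_std(v + 5, m)$data, ls, tolerance = 1e-8)
  expect_error(local_std(v, array(0, c(4, 4, 4))), "zero")
})

test_that("a planted template copy scores 1 and its negation -1", {
  tpl <- fx_template()
  mask <- fx_mask()
  wedge <- c(39, 39)
  # wedge-filter the template exactly as the engine does, then plant it
  wm <- build_wedge_mask(dim(tpl), wedge)$data
  tw <- Re(tomatch:::fft3(tomatch:::fft3(tpl$data) * as.vector(wm),
                          inverse = TRUE))
  dim(tw) <- dim(tpl)
  tomo <- array(0, c(64, 64, 64))
  tomo[17:48, 17:48, 17:48] <- tw  # center lands at 0-based (32, 32, 32)
  tv <- density_volume(tomo, 13.8)
  sc <- lcc_single_orientation(tv, tpl, mask, wedge = wedge)
  expect_equal(sc$data[33, 33, 33], 1, tolerance = 1e-3)
  expect_equal(max(sc$data), 1, tolerance = 1e-3)
  scn <- lcc_single_orientation(density_volume(-tomo, 13.8), tpl, mask,
                                wedge = wedge)
  expect_equal(scn$data[33, 33, 33], -1, tolerance = 1e-3)
})

test_that("FFT scoring equals the direct-space local correlation at
           sampled positions", {
  set.seed(3)
  n <- 24
  L <- 8
  v <- array(rnorm(n^3), rep(n, 3))
  tpl <- array(rnorm(L^3), rep(L, 3))
  m <- build_spherical_mask(L, 6, 1, 1)$data
  sc <- lcc_single_orientation(density_volume(v, 1), density_volume(tpl, 1),
                               m)$data
  P <- sum(m)
  mu_t <- sum(m * tpl) / P
  sig_t <- sqrt(sum(m * (tpl - mu_t)^2) / P)
  c0 <- L %/% 2
  direct <- function(x, y, z) {  # 0-based, valid region only
    num <- 0; s1 <- 0; s2 <- 0
    for (k in 0:(L - 1)) for (j in 0:(L - 1)) for (i in 0:(L - 1)) {
      vi <- v[x + i - c0 + 1, y + j - c0 + 1, z + k - c0 + 1]
      w <- m[i + 1, j + 1, k + 1]
      num <- num + w * (tpl[i + 1, j + 1, k + 1] - mu_t) * vi
      s1 <- s1 + w * vi
      s2 <- s2 + w * vi^2
    }
    sig_v <- sqrt(max(0, s2 / P - (s1 / P)^2))
    num / (P * sig_t * sig_v)
  }
  pts <- matrix(c(12, 12, 12, 5, 8, 17, 19, 4, 10, 7, 15, 6, 10, 18, 13),
                ncol = 3, byrow = TRUE)
  for (r in seq_len(nrow(pts)))
    expect_lt(abs(sc[pts[r, 1] + 1, pts[r, 2] + 1, pts[r, 3] + 1] -
                    direct(pts[r, 1], pts[r, 2], pts[r, 3])), 1e-5)
})

test_that("run_match reduces to the single-orientation score for |A| = 1
           and the maximum is monotone in the orientation set", {
  ph <- fx_small_phantom()
  tpl <- fx_template()
  mask <- fx_mask()
  one <- tomatch:::new_orientation_set(
    tibble::tibble(phi = 0, theta = 0, psi = 0), NA, "loaded")
  job1 <- match_job(ph$tomogram, tpl, mask, one, wedge = c(39, 39))
  r1 <- run_match(job1)
  direct <- lcc_single_orientation(ph$tomogram, tpl, mask, wedge = c(39, 39))
  expect_equal(r1$lcc_max$data, direct$data, tolerance = 1e-12)
  expect_true(all(r1$angle_index == 0))

  few <- tomatch:::new_orientation_set(
    tibble::tibble(phi = c(0, 45, 120), theta = c(0, 60, 100),
                   psi = c(0, 30, 200)), NA, "loaded")
  job3 <- match_job(ph$tomogram, tpl, mask, few, wedge = c(39, 39))
  r3 <- run_match(job3)
  expect_true(all(r3$lcc_max$data >= r1$lcc_max$data - 1e-12))
  expect_true(all(r3$angle_index %in% 0:2))
  expect_true(all(abs(r3$lcc_max$data[r3$lcc_max$data > -1]) <= 1 + 1e-6))
})

test_that("scores are invariant to affine intensity transforms of the
           tomogram", {
  ph <- fx_small_phantom()
  tpl <- fx_template()
  mask <- fx_mask()
  one <- tomatch:::new_orientation_set(
    tibble::tibble(phi = 10, theta = 40, psi = 70), NA, "loaded")
  job <- match_job(ph$tomogram, tpl, mask, one, wedge = c(39, 39))
  r <- run_match(job)
  t2 <- density_volume(2.5 * ph$tomogram$data + 7, ph$tomogram$voxel_size)
  job2 <- match_job(t2, tpl, mask, one, wedge = c(39, 39))
  r2 <- run_match(job2)
  sel <- r$lcc_max$data > -1
  expect_lt(max(abs(r$lcc_max$data[sel] - r2$lcc_max$data[sel])), 1e-5)
})

test_that("matching locates a planted particle at its orientation", {
  tpl <- fx_template()
  mask <- fx_mask()
  ors <- generate_orientation_set(40)
  # plant at an orientation that is in the search set
  target <- 17L
  ph_or <- ors[target, ]
  sig <- array(0, c(64, 64, 64))
  rt <- rotate_volume(tpl$data, c(ph_or$phi, ph_or$theta, ph_or$psi))
  sig[25:56, 21:52, 17:48] <- rt  # 0-based center (40, 36, 32)
  wm <- build_wedge_mask(c(64, 64, 64), c(39, 39))$data
  sig <- Re(tomatch:::fft3(tomatch:::fft3(sig) * as.vector(wm), inverse = TRUE))
  dim(sig) <- c(64, 64, 64)
  set.seed(20)
  tomo <- density_volume(sig + rnorm(64^3, 0, sqrt(var(as.vector(sig)) / 4)),
                         13.8)
  job <- match_job(tomo, tpl, mask, ors, wedge = c(39, 39))
  res <- run_match(job)
  w <- which(res$lcc_max$data == max(res$lcc_max$data), arr.ind = TRUE)[1, ] - 1
  expect_lte(sqrt(sum((w - c(40, 36, 32))^2)), 1)
  # best orientation at the peak is close to the planted one
  best <- res$angle_index[w[1] + 1, w[2] + 1, w[3] + 1] + 1
  qb <- euler_to_quaternion(ors[best, ])
  qt <- euler_to_quaternion(ph_or)
  expect_lt(rotation_geodesic(qb, qt)[1, 1], 40)
})

test_that("subvolume and angle splitting reproduce the serial result", {
  ph <- fx_small_phantom()
  tpl <- fx_template()
  mask <- fx_mask()
  few <- generate_orientation_set(60)
  job <- match_job(ph$tomogram, tpl, mask, few, wedge = c(39, 39),
                   split = c(2, 2, 1))
  serial <- run_match(job)
  split2 <- split_and_merge(job)
  sel <- serial$lcc_max$data > -1
  expect_lt(max(abs(serial$lcc_max$data[sel] - split2$lcc_max$data[sel])), 1e-6)

  # 1x1x1 spatial split with 2 angle chunks must be exact
  job1 <- match_job(ph$tomogram, tpl, mask, few, wedge = c(39, 39))
  aspl <- split_and_merge(job1, angle_chunks = 2)
  expect_identical(aspl$lcc_max$data, serial$lcc_max$data)
  expect_identical(aspl$angle_index, serial$angle_index)
})
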