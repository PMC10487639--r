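test_that("electron wavelength matches the relativistic formula", {
  expect_equal(electron_wavelength(200), 0.02508, tolerance = 1e-3)
  expect_equal(electron_wavelength(300), 0.01969, tolerance = 1e-3)
  # strictly decreasing in voltage
  v <- seq(80, 300, by = 20)
  expect_true(all(diff(electron_wavelength(v)) < 0))
  expect_error(electron_wavelength(0), "positive")
})

test_that("CTF has amplitude-contrast magnitude at k = 0 and a bracketed
           first zero", {
  ctf <- ctf_params(defocus = 3, voltage = 200, cs = 2.7,
                    amplitude_contrast = 0.08)
  expect_equal(abs(ctf_modulation(0, ctf)), 0.08)
  expect_true(all(abs(ctf_modulation(seq(0, 0.5, by = 1e-3), ctf)) <= 1 + 1e-12))

  # independent bracketing root-finder on the same closed form
  a <- 0.08
  lambda <- electron_wavelength(200)
  chi <- function(k) pi * lambda * 3e4 * k^2 - pi / 2 * 2.7e7 * lambda^3 * k^4
  f <- function(k) sqrt(1 - a^2) * sin(chi(k)) + a * cos(chi(k))
  ks <- seq(1e-6, 0.2, by = 1e-6)
  i <- which(sign(f(ks)) != sign(f(1e-9)))[1]
  k0_oracle <- uniroot(f, c(ks[i - 1], ks[i]), tol = 1e-14)$root
  expect_equal(ctf_first_zero(ctf), k0_oracle, tolerance = 1e-4 / k0_oracle)

  # truncation: exactly zero beyond the first zero
  k0 <- ctf_first_zero(ctf)
  expect_identical(ctf_modulation(1.5 * k0, ctf,
                                  truncate_after_first_zero = TRUE), 0)
  expect_false(ctf_modulation(1.5 * k0, ctf) == 0)
  # continuous below the first zero
  kk <- seq(0, k0 * 0.99, length.out = 500)
  expect_lt(max(abs(diff(ctf_modulation(kk, ctf, TRUE)))), 0.02)
})

test_that("identity modulation reduces build_template to Fourier-crop
           resampling", {
  set.seed(10)
  # smooth map so the Fourier-crop comparison is well-conditioned
  n <- 32
  ax <- (0:(n - 1)) - n %/% 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  m <- exp(-d2 / 50) + 0.5 * exp(-((sqrt(d2) - 8)^2) / 8)
  map <- density_volume(array(m, rep(n, 3)), voxel_size = 1.85)
  # chi == 0 (no defocus, no aberration) and pure amplitude contrast give a
  # constant modulation of -1 under the weak-phase convention
  flat_ctf <- ctf_params(defocus = 0, voltage = 200, cs = 0,
                         amplitude_contrast = 1)
  out1 <- build_template(map, output_voxel = 3.7, ctf = flat_ctf,
                         truncate_ctf = FALSE)
  out2 <- build_template(map, output_voxel = 3.7)  # plain resampling
  expect_equal(out1$data, -out2$data, tolerance = 1e-10)
  expect_equal(dim(out1), c(16, 16, 16))
})

test_that("8x downsampling of a 1.85 A map records a 14.8 A voxel", {
  map <- density_volume(array(rnorm(64^3), rep(64, 3)), voxel_size = 1.85)
  out <- build_template(map, output_voxel = 14.8)
  expect_equal(out$voxel_size, 14.8)
  expect_equal(dim(out), c(8, 8, 8))
})

test_that("low-pass filtered templates carry no power beyond the cutoff", {
  set.seed(11)
  n <- 48
  map <- density_volume(array(rnorm(n^3), rep(n, 3)), voxel_size = 2)
  out <- build_template(map, lowpass = 10)  # cutoff 0.1 1/A, Nyquist 0.25
  ff <- tomatch:::fft3(out$data)
  kx <- tomatch:::fft_freq_index(n) / (n * 2)
  kmag <- sqrt(outer(outer(kx^2, kx^2, "+"), kx^2, "+"))
  p_out <- sum(Mod(ff[kmag > 1 / 10 + 2 / (n * 2)])^2)
  expect_lt(p_out / sum(Mod(ff)^2), 1e-6)
  expect_error(build_template(map, lowpass = 3), "Nyquist")
})

test_that("build_template is linear in the map intensity", {
  set.seed(12)
  map <- density_volume(array(rnorm(24^3), rep(24, 3)), voxel_size = 2)
  ctf <- ctf_params(3, 200, 2.7, 0.08)
  t1 <- build_template(map, output_voxel = 4, ctf = ctf, lowpass = 10)
  map3 <- density_volume(map$data * 3, 2)
  t3 <- build_template(map3, output_voxel = 4, ctf = ctf, lowpass = 10)
  expect_equal(t3$data, 3 * t1$data, tolerance = 1e-10)
})

test_that("spherical masks have a unit core, clamped support and the
           analytic volume", {
  m <- build_spherical_mask(32, diameter = 350, voxel_size = 13.8,
                            soft_edge_sigma = 1.5)
  c0 <- 16 + 1
  expect_equal(m$data[c0, c0, c0], 1)
  expect_true(all(m$data >= 0 & m$data <= 1))
  r <- (350 / 2) / 13.8
  ax <- (0:31) - 16
  dist <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  expect_true(all(m$data[dist > r + 3 * 1.5] == 0))
  # hard sphere: voxel count close to the analytic ball volume
  h <- build_spherical_mask(32, 350, 13.8, soft_edge_sigma = 0)
  expect_equal(sum(h$data), 4 / 3 * pi * r^3, tolerance = 0.05)
  expect_error(build_spherical_mask(8, 350, 13.8), "larger than")
})

test_that("missing-wedge masks have the right pass fraction and symmetry", {
  expect_equal(missing_wedge_angles(c(-51, 51)), c(39, 39))
  wm0 <- build_wedge_mask(c(16, 16, 16), c(0, 0))
  expect_true(all(wm0$data == 1))

  wm <- build_wedge_mask(c(48, 48, 48), c(39, 39))$data
  kx <- tomatch:::fft_freq_index(48) / 48
  r2 <- outer(outer(kx^2, kx^2, "+"), kx^2, "+")
  sel <- r2 > 0 & r2 < 0.45^2
  expect_equal(mean(wm[sel]), (180 - 2 * 39) / 180, tolerance = 0.02)

  # Hermitian symmetry: mask(k) == mask(-k) exactly, on every voxel
  idx <- tomatch:::fft_freq_index(48)
  neg <- (((-idx) %% 48) + 1)  # position of the negated frequency
  flipped <- wm[neg[1:48], neg[1:48], neg[1:48]]
  expect_identical(wm[1:48, 1:48, 1:48], flipped)
})
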