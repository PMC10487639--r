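test_that("MRC volumes survive a write/read round trip", {
  set.seed(1)
  v <- density_volume(array(rnorm(16^3), rep(16, 3)), voxel_size = 13.8)
  path <- tempfile(fileext = ".mrc")
  on.exit(unlink(path))
  write_mrc(v, path)
  back <- read_mrc(path)
  # data stored as float32: exact at float precision
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$voxel_size, 13.8, tolerance = 1e-6)
  expect_equal(dim(back), c(16, 16, 16))
})

test_that("MRC writer records header statistics and arbitrary dims", {
  v <- density_volume(array(2.5, c(12, 14, 10)), voxel_size = 14.8)
  path <- tempfile(fileext = ".mrc")
  on.exit(unlink(path))
  write_mrc(v, path)
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 1024)
  close(con)
  dmean <- readBin(hdr[85:88], "numeric", 1, size = 4, endian = "little")
  expect_equal(dmean, 2.5, tolerance = 1e-6)
  back <- read_mrc(path)
  expect_equal(dim(back), c(12, 14, 10))
  expect_true(all(back$data == back$data[1]))
})

test_that("corrupt or truncated MRC files error without partial volumes", {
  v <- density_volume(array(0, c(8, 8, 8)), 1)
  path <- tempfile(fileext = ".mrc")
  on.exit(unlink(path))
  write_mrc(v, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:(1024 + 100)], path)
  expect_error(read_mrc(path), "truncated")
  expect_error(read_mrc(tempfile()), "not found")
})

test_that("anisotropic cells are rejected with the offending field named", {
  v <- density_volume(array(0, c(8, 8, 8)), 2)
  path <- tempfile(fileext = ".mrc")
  on.exit(unlink(path))
  write_mrc(v, path)
  raw <- readBin(path, "raw", file.size(path))
  # overwrite cella x (word 11) with a different length
  raw[41:44] <- writeBin(99, raw(), size = 4, endian = "little")
  writeBin(raw, path)
  expect_error(read_mrc(path), "cella")
})

test_that("XML particle lists round-trip exactly", {
  pl <- particle_list(tomogram = "t1", x = c(10, 50), y = c(20, 60),
                      z = c(30, 70), phi = c(15.5, 240), theta = c(30, 120),
                      psi = c(290, 10), score = c(0.9, 0.5),
                      voxel_size = 13.8, tomogram_dims = c(128, 128, 128))
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  write_particle_xml(pl, path)
  back <- read_particle_xml(path)
  expect_equal(as.data.frame(back), as.data.frame(pl), tolerance = 1e-12)
  expect_equal(attr(back, "voxel_size"), 13.8)
  expect_equal(attr(back, "tomogram_dims"), c(128L, 128L, 128L))
})

test_that("STAR conversion is lossless up to the Euler round trip and
           converts units exactly", {
  pl <- particle_list(tomogram = "t1", x = 10, y = 20, z = 30,
                      phi = 0, theta = 0, psi = 0, score = 0.8,
                      voxel_size = 13.8)
  path <- tempfile(fileext = ".star")
  on.exit(unlink(path))
  # identity orientation in angstrom: coordinates multiply by voxel size
  write_particle_star(pl, path, coordinate_unit = "angstrom")
  lines <- readLines(path)
  row <- strsplit(lines[grep("^t1", lines)], "\t")[[1]]
  expect_equal(as.numeric(row[2:4]), c(138, 276, 414))
  expect_equal(as.numeric(row[5:7]), c(0, 0, 0))
  back <- read_particle_star(path, coordinate_unit = "angstrom",
                             voxel_size = 13.8)
  expect_equal(back$x, 10, tolerance = 1e-9)

  # voxel-unit round trip with nontrivial orientations
  set.seed(6)
  pl2 <- particle_list(tomogram = "t2", x = runif(5, 0, 100),
                       y = runif(5, 0, 100), z = runif(5, 0, 100),
                       phi = runif(5, 0, 360), theta = runif(5, 0, 180),
                       psi = runif(5, 0, 360), score = runif(5, 0, 1),
                       voxel_size = 13.8)
  write_particle_star(pl2, path)
  back2 <- read_particle_star(path)
  expect_equal(back2$x, pl2$x, tolerance = 1e-5)
  for (i in 1:5) {
    R1 <- euler_to_matrix(pl2$phi[i], pl2$theta[i], pl2$psi[i])
    R2 <- euler_to_matrix(back2$phi[i], back2$theta[i], back2$psi[i])
    expect_lt(max(abs(R1 - R2)), 1e-6)
  }
})

test_that("empty particle lists produce valid documents with zero rows", {
  pl <- particle_list(tomogram = character(), x = numeric(), y = numeric(),
                      z = numeric(), phi = numeric(), theta = numeric(),
                      psi = numeric(), score = numeric(), voxel_size = 10)
  xml_path <- tempfile(fileext = ".xml")
  star_path <- tempfile(fileext = ".star")
  on.exit(unlink(c(xml_path, star_path)))
  write_particle_xml(pl, xml_path)
  expect_equal(nrow(read_particle_xml(xml_path)), 0)
  write_particle_star(pl, star_path)
  expect_equal(nrow(read_particle_star(star_path)), 0)
})

test_that("file-level XML <-> STAR conversion round-trips positions and
           orientations", {
  set.seed(8)
  pl <- particle_list(tomogram = "t", x = round(runif(4, 0, 90)),
                      y = round(runif(4, 0, 90)), z = round(runif(4, 0, 90)),
                      phi = runif(4, 0, 360), theta = runif(4, 0, 180),
                      psi = runif(4, 0, 360), score = runif(4),
                      voxel_size = 13.8, tomogram_dims = c(96, 96, 96))
  xml1 <- tempfile(fileext = ".xml")
  star <- tempfile(fileext = ".star")
  xml2 <- tempfile(fileext = ".xml")
  on.exit(unlink(c(xml1, star, xml2)))
  write_particle_xml(pl, xml1)
  convert_particles(xml1, star, "xml_to_star")
  convert_particles(star, xml2, "star_to_xml")
  back <- read_particle_xml(xml2)
  expect_equal(back$x, pl$x)  # positions exact
  expect_equal(back$y, pl$y)
  expect_equal(back$z, pl$z)
  for (i in seq_len(nrow(pl))) {   # orientations to 1e-8 degrees
    R1 <- euler_to_matrix(pl$phi[i], pl$theta[i], pl$psi[i])
    R2 <- euler_to_matrix(back$phi[i], back$theta[i], back$psi[i])
    expect_lt(max(abs(R1 - R2)), 1e-8)
  }
})
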