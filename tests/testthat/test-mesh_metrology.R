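test_that("unit cube has the textbook area, volume and diagonal", {
  m <- unit_cube()
  expect_true(is_watertight(m))
  sv <- surface_and_volume(m)
  expect_equal(sv$area, 6)
  expect_equal(sv$volume, 1)
  expect_equal(longest_axis(m), sqrt(3))
})

test_that("icosphere refinement converges to the closed forms", {
  ic <- make_icosphere(radius = 2, subdivisions = 4)
  sv <- surface_and_volume(ic)
  expect_lt(abs(sv$area - 4 * pi * 4) / (4 * pi * 4), 0.005)
  expect_lt(abs(sv$volume - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.005)
})

test_that("open meshes keep their area but refuse a volume", {
  m <- unit_cube()
  open <- tri_mesh(m$vertices, m$faces[-1, ])
  expect_false(is_watertight(open))
  expect_equal(mesh_area(open), 5.5)   # 11 of 12 half-face triangles
  expect_error(mesh_volume(open), "watertight")
  expect_error(surface_and_volume(open), "watertight")
})

test_that("area and volume scale as s^2 and s^3; volume ignores winding", {
  m <- make_icosphere(1, 2)
  base <- surface_and_volume(m)
  for (s in c(0.5, 2)) {
    scaled <- tri_mesh(m$vertices * s, m$faces)
    sv <- surface_and_volume(scaled)
    expect_equal(sv$area, base$area * s^2, tolerance = 1e-12)
    expect_equal(sv$volume, base$volume * s^3, tolerance = 1e-12)
  }
  flipped <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), base$volume, tolerance = 1e-12)
})

test_that("step height recovers ideal gauge-cube steps exactly", {
  for (h in list(c(1.50, 1.00), c(1.10, 1.00), c(1.05, 1.00))) {
    cubes <- make_step_cubes(h, noise_sd = 0)
    sh <- step_height(cubes$mesh, cubes$top, cubes$reference)
    expect_equal(sh$mean, h[1] - h[2], tolerance = 1e-12)
    expect_equal(sh$sd, 0)
    expect_gt(sh$n_top, 0); expect_gt(sh$n_ref, 0)
  }
})

test_that("step height is translation-invariant and antisymmetric", {
  cubes <- make_step_cubes(c(1.50, 1.00), noise_sd = 0.005,
                           n_vertices = 1000, seed = 7)
  sh <- step_height(cubes$mesh, cubes$top, cubes$reference)

  shifted <- tri_mesh(sweep(cubes$mesh$vertices, 2, c(3, -2, 10), `+`),
                      cubes$mesh$faces)
  shift_region <- function(r) region_spec(r$min + c(3, -2, 10),
                                          r$max + c(3, -2, 10))
  sh2 <- step_height(shifted, shift_region(cubes$top),
                     shift_region(cubes$reference))
  expect_equal(sh2$mean, sh$mean, tolerance = 1e-12)
  expect_equal(sh2$sd, sh$sd, tolerance = 1e-12)

  rev <- step_height(cubes$mesh, cubes$reference, cubes$top)
  expect_equal(rev$mean, -sh$mean, tolerance = 1e-12)

  same <- step_height(cubes$mesh, cubes$top, cubes$top)
  expect_equal(same$mean, 0)
})

test_that("noisy step heights carry the expected spread", {
  # sigma = 5 um per vertex; region sds combine in quadrature to sqrt(2)*sigma
  cubes <- make_step_cubes(c(1.05, 1.00), noise_sd = 0.005,
                           n_vertices = 10000, seed = 2)
  sh <- step_height(cubes$mesh, cubes$top, cubes$reference)
  expect_lt(abs(sh$mean - 0.050), 3 * 0.005 / sqrt(10000))
  expect_lt(abs(sh$sd - sqrt(2) * 0.005) / (sqrt(2) * 0.005), 0.2)
})

test_that("empty regions are rejected by name", {
  cubes <- make_step_cubes(c(1.5, 1.0))
  nowhere <- region_spec(c(100, 100, 100), c(101, 101, 101))
  expect_error(step_height(cubes$mesh, nowhere, cubes$reference), "top")
  expect_error(step_height(cubes$mesh, cubes$top, nowhere), "reference")
})

test_that("longest axis equals the brute-force pairwise maximum", {
  # the published convention: longest body axis of the final mesh
  two <- tri_mesh(rbind(c(0, 0, 0), c(0, 0, 36.3)),
                  matrix(integer(0), 0, 3))
  expect_equal(longest_axis(two), 36.3)

  brute <- function(v) max(dist(v))
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(rnorm(600), 200, 3)
    m <- tri_mesh(v, matrix(integer(0), 0, 3))
    expect_equal(longest_axis(m), brute(v), tolerance = 1e-12)
    # the support-vertex reduction path agrees with brute force too
    expect_equal(longest_axis(m, exact_limit = 10L), brute(v),
                 tolerance = 1e-9)
  }
})

test_that("PLY and OBJ files round-trip through the readers", {
  m <- unit_cube()

  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, ply)
  r <- read_ply(ply)
  expect_equal(r$vertices, m$vertices, ignore_attr = TRUE)
  expect_true(all(r$faces == m$faces))

  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, obj)
  r2 <- read_mesh(obj)
  expect_equal(r2$vertices, m$vertices, ignore_attr = TRUE)
  expect_true(all(r2$faces == m$faces))
})

test_that("binary little-endian PLY is read correctly", {
  m <- unit_cube()
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  r <- read_ply(f)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-7, ignore_attr = TRUE)
  expect_true(all(r$faces == m$faces))
  expect_true(is_watertight(r))
})

test_that("quads in OBJ files are fan-triangulated", {
  f <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1/1 2/2 3/3 4/4"), f)
  m <- read_obj(f)
  expect_equal(nrow(m$faces), 2)
  expect_equal(mesh_area(m), 1)
})
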