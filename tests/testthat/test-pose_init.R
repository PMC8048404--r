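make_intrinsics <- function() {
  camera_intrinsics("FLIR", "BFS-U3-200S6C-C", "SN0001",
                    focal_length_mm = 35.0, focal_length_35mm = 95.0,
                    sensor_width_mm = 13.1,
                    image_width_px = 5472, image_height_px = 3648)
}

pose_invariant_errors <- function(pose, radius) {
  R <- pose$rotation; ctr <- pose$centre
  look <- -R[, 3]                              # camera looks along local -Z
  to_origin <- -ctr / sqrt(sum(ctr^2))
  c(orth = max(abs(crossprod(R) - diag(3))),
    det = abs(det(R) - 1),
    sphere = abs(sqrt(sum(ctr^2)) - radius),
    lookat = acos(min(1, sum(look * to_origin))))
}

test_that("single poses match their closed forms", {
  home <- camera_pose(0, 0, 150)
  expect_equal(home$centre, c(0, 0, 150))
  expect_equal(home$rotation, diag(3))

  # half a turn about Y: opposite side, viewing direction reversed
  back <- camera_pose(0, 180, 150)
  expect_equal(back$centre, c(0, 0, -150), tolerance = 1e-12)
  expect_equal(-back$rotation[, 3], c(0, 0, 1), tolerance = 1e-12)

  for (ang in list(c(30, 45), c(-40, 200), c(50, 342))) {
    e <- pose_invariant_errors(camera_pose(ang[1], ang[2], 87.5), 87.5)
    expect_lt(e["orth"], 1e-9)
    expect_lt(e["sphere"], 1e-9)
    expect_lt(e["lookat"], 1e-7)
  }
})

test_that("the full 6 x 20 scan grid satisfies all pose invariants", {
  cfg <- scan_config(seq(-40, 60, by = 20), seq(0, 342, by = 18), 150,
                     make_intrinsics())
  scene <- pose_grid(cfg)
  expect_equal(length(scene$poses), 120)
  expect_equal(nrow(scene$views), 120)
  errs <- vapply(scene$poses, pose_invariant_errors, numeric(4), radius = 150)
  expect_lt(max(errs["orth", ]), 1e-9)
  expect_lt(max(errs["det", ]), 1e-9)
  expect_lt(max(errs["sphere", ]), 1e-9)
  expect_lt(max(errs["lookat", ]), 1e-7)

  # distinct grid points never produce coincident camera centres
  ctrs <- t(vapply(scene$poses, `[[`, numeric(3), "centre"))
  dmin <- min(dist(ctrs))
  expect_gt(dmin, 1e-6)
})

test_that("equatorial quarter-turn poses are mutually orthogonal", {
  cfg <- scan_config(0, c(0, 90, 180, 270), 100, make_intrinsics())
  scene <- pose_grid(cfg)
  ctrs <- t(vapply(scene$poses, `[[`, numeric(3), "centre"))
  expect_lt(abs(sum(ctrs[1, ] * ctrs[2, ])), 1e-9)
  expect_lt(abs(sum(ctrs[2, ] * ctrs[3, ])), 1e-9)
  expect_lt(max(abs(ctrs[1, ] + ctrs[3, ])), 1e-9)  # antipodal pair
})

test_that("poses are periodic in the Y rotation", {
  a <- camera_pose(20, 30, 50)
  b <- camera_pose(20, 390, 50)
  expect_equal(a$centre, b$centre, tolerance = 1e-9)
  expect_equal(a$rotation, b$rotation, tolerance = 1e-9)
})

test_that("scan_config validates its grid", {
  expect_error(scan_config(0, c(0, 90), 100, make_intrinsics(),
                           image_names = "only_one.png"), "image names")
  expect_warning(scan_config(c(-60, 60), 0, 100, make_intrinsics()),
                 "100 degree")
})

test_that(".sfm files round-trip and are byte-stable", {
  cfg <- scan_config(seq(-40, 60, by = 20), seq(0, 342, by = 18), 150,
                     make_intrinsics())
  scene <- pose_grid(cfg)
  f1 <- withr::local_tempfile(fileext = ".sfm")
  f2 <- withr::local_tempfile(fileext = ".sfm")
  write_sfm(scene, f1); write_sfm(scene, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  doc <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_length(doc$poses, 120)
  expect_length(doc$intrinsics, 1)

  back <- read_sfm(f1)
  for (i in c(1, 37, 120)) {
    expect_equal(back$poses[[i]]$rotation, scene$poses[[i]]$rotation,
                 tolerance = 1e-9)
    expect_equal(back$poses[[i]]$centre, scene$poses[[i]]$centre,
                 tolerance = 1e-9)
  }
  expect_equal(back$views$name, scene$views$name)
})

test_that("EXIF tags round-trip without touching pixel data", {
  f <- withr::local_tempfile(fileext = ".png")
  set.seed(77)
  png::writePNG(matrix(runif(256), 16, 16), f)
  pixels_before <- png::readPNG(f)

  write_exif(f, make_intrinsics())
  ex <- read_exif(f)
  expect_equal(ex$Make, "FLIR")
  expect_equal(ex$Model, "BFS-U3-200S6C-C")
  expect_equal(ex$CameraSerialNumber, "SN0001")
  expect_equal(ex$FocalLength, 35.0)
  expect_equal(ex$FocalLengthIn35mmFormat, 95)
  expect_equal(ex$SensorWidth, 13.1)
  expect_identical(png::readPNG(f), pixels_before)

  # re-tagging replaces the metadata instead of accumulating chunks
  write_exif(f, list(Make = "X", Model = "Y", CameraSerialNumber = "Z",
                     FocalLength = 50, FocalLengthIn35mmFormat = 135,
                     SensorWidth = 10))
  expect_equal(read_exif(f)$FocalLength, 50)
  expect_identical(png::readPNG(f), pixels_before)
})

test_that("missing metadata fields are reported by name", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f)
  expect_error(write_exif(f, list(Make = "A", Model = "B", FocalLength = 35,
                                  FocalLengthIn35mmFormat = 95,
                                  SensorWidth = 13.1)),
               "CameraSerialNumber")
  expect_error(write_exif("no_such_file.png", make_intrinsics()),
               "no such file")
})
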