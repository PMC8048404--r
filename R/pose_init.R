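## rotation about the world X axis (degrees)
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

## rotation about the world Y axis (degrees)
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' Camera intrinsics shared by all views of a scan
#'
#' One intrinsics record is shared by every view: all EDOF images of a scan
#' must carry the same camera identity so reconstruction software solves the
#' intrinsics once and applies them to every scene. `focal_length_35mm` is
#' user-supplied configuration (read off the lens/camera documentation), not
#' derived from the sensor crop factor.
#'
#' @param make,model,serial camera identification strings.
#' @param focal_length_mm physical focal length of the lens, mm.
#' @param focal_length_35mm 35 mm-equivalent focal length, mm.
#' @param sensor_width_mm physical sensor width, mm.
#' @param image_width_px,image_height_px image dimensions in pixels.
#' @return an object of class `"camera_intrinsics"`.
#' @export
camera_intrinsics <- function(make, model, serial,
                              focal_length_mm, focal_length_35mm,
                              sensor_width_mm,
                              image_width_px, image_height_px) {
  stopifnot(focal_length_mm > 0, focal_length_35mm > 0, sensor_width_mm > 0,
            image_width_px > 0, image_height_px > 0)
  structure(list(make = make, model = model, serial = serial,
                 focal_length_mm = focal_length_mm,
                 focal_length_35mm = focal_length_35mm,
                 sensor_width_mm = sensor_width_mm,
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px)),
            class = "camera_intrinsics")
}

#' Analytic camera pose for one gimbal orientation
#'
#' The scanner rotates the specimen on a two-axis gimbal while the camera is
#' fixed; under the equivalent-camera-motion model the specimen's rotation
#' by (x tilt, y rotation) is inverted onto the camera, which therefore sits
#' on a sphere of radius `radius` around the specimen and always looks at
#' the origin. World frame: right-handed, +Y up (the gimbal's vertical
#' axis), +Z from the specimen towards the camera home position. The camera
#' looks along its local -Z; the look-at up vector is world +Y, replaced by
#' world +X if the viewing axis is (numerically) vertical.
#'
#' `centre = R_y(-y) R_x(-x) (0, 0, radius)`; X tilt is applied before Y
#' rotation, matching the physical nesting of the stages.
#'
#' @param x_deg tilt about the horizontal X axis, degrees.
#' @param y_deg rotation about the vertical Y axis, degrees.
#' @param radius camera-to-specimen distance, mm (> 0).
#' @return object of class `"camera_pose"`: `rotation` (3x3 orthonormal
#'   camera-to-world matrix, det +1) and `centre` (camera position, mm).
#' @export
camera_pose <- function(x_deg, y_deg, radius) {
  stopifnot(radius > 0)
  centre <- as.vector(rot_y(-y_deg) %*% rot_x(-x_deg) %*% c(0, 0, radius))
  zc <- centre / sqrt(sum(centre^2))   # camera +Z points away from target
  up <- c(0, 1, 0)
  if (sqrt(sum(crossp(up, zc)^2)) < 1e-6) up <- c(1, 0, 0)
  xc <- crossp(up, zc); xc <- xc / sqrt(sum(xc^2))
  yc <- crossp(zc, xc)
  structure(list(rotation = cbind(xc, yc, zc, deparse.level = 0),
                 centre = centre),
            class = "camera_pose")
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Scan configuration for a two-axis gimbal acquisition
#'
#' Describes the pose grid of a scan: the X-tilt angles (the scanner covers
#' an angular range of up to 100 degrees about X; wider spans trigger a
#' warning since the illumination dome no longer backs every view), the
#' Y-rotation angles (any orientation about the vertical axis), the camera
#' working distance, and the shared intrinsics. Image names follow the pose
#' grid in row-major order (X outer, Y inner) and default to the
#' `x{+ddd}_y{ddd}.png` convention.
#'
#' @param x_angles_deg,y_angles_deg numeric angle vectors (non-empty).
#' @param radius camera-to-centre distance, mm.
#' @param intrinsics a [camera_intrinsics()].
#' @param image_names optional character vector, one name per (x, y) pair in
#'   row-major order.
#' @return an object of class `"scan_config"`.
#' @export
scan_config <- function(x_angles_deg, y_angles_deg, radius, intrinsics,
                        image_names = NULL) {
  stopifnot(length(x_angles_deg) >= 1L, length(y_angles_deg) >= 1L,
            radius > 0, inherits(intrinsics, "camera_intrinsics"))
  if (diff(range(x_angles_deg)) > 100)
    warning("scan_config: X-tilt span exceeds the scanner's 100 degree range")
  n <- length(x_angles_deg) * length(y_angles_deg)
  if (is.null(image_names)) {
    grid <- expand.grid(y = y_angles_deg, x = x_angles_deg)  # y varies fastest
    image_names <- sprintf("x%+04d_y%03d.png", round(grid$x), round(grid$y))
  }
  if (length(image_names) != n)
    stop("scan_config: expected ", n, " image names, got ", length(image_names))
  structure(list(x_angles_deg = x_angles_deg, y_angles_deg = y_angles_deg,
                 radius = radius, intrinsics = intrinsics,
                 image_names = image_names),
            class = "scan_config")
}

#' Compute the full pose grid of a scan as an SfM scene
#'
#' One [camera_pose()] per (x, y) angle pair, in row-major order (X outer,
#' Y inner), bundled with the shared intrinsics into a serializable scene
#' (see [write_sfm()]). All camera centres lie on the sphere of the
#' configured radius and every pose looks at the origin. The poses are
#' initialization priors for structure-from-motion refinement, not metric
#' claims beyond the rig model.
#'
#' @param config a [scan_config()].
#' @return an object of class `"sfm_scene"`: `views` (data frame with
#'   `name`, `view_id`, `intrinsic_id`, `pose_id`), `intrinsics` (single
#'   record), `poses` (list of `"camera_pose"`).
#' @export
pose_grid <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  grid <- expand.grid(y = config$y_angles_deg, x = config$x_angles_deg)
  n <- nrow(grid)
  poses <- lapply(seq_len(n), function(i)
    camera_pose(grid$x[i], grid$y[i], config$radius))
  views <- data.frame(name = config$image_names,
                      view_id = seq_len(n),
                      intrinsic_id = 1L,
                      pose_id = seq_len(n),
                      x_deg = grid$x, y_deg = grid$y)
  structure(list(views = views, intrinsics = config$intrinsics,
                 poses = poses),
            class = "sfm_scene")
}

#' @export
print.sfm_scene <- function(x, ...) {
  cat(sprintf("<sfm_scene> %d views, 1 intrinsics record, %d poses\n",
              nrow(x$views), length(x$poses)))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize an SfM scene to an AliceVision-dialect .sfm file
#'
#' Writes a JSON document with a version header, a `views` array, a single
#' `intrinsics` record, and a `poses` array whose rotations are stored as 9
#' row-major numbers and centres as 3 numbers (all formatted as strings, as
#' the dialect expects). Output is byte-stable: two writes of the same scene
#' produce identical files. The file can be loaded by photogrammetry
#' software as a camera-pose prior.
#'
#' @param scene an [pose_grid()] scene.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sfm <- function(scene, path) {
  stopifnot(inherits(scene, "sfm_scene"))
  intr <- scene$intrinsics
  focal_px <- intr$focal_length_mm / intr$sensor_width_mm * intr$image_width_px
  doc <- list(
    version = c("1", "0", "0"),
    views = lapply(seq_len(nrow(scene$views)), function(i) {
      v <- scene$views[i, ]
      list(viewId = as.character(v$view_id),
           poseId = as.character(v$pose_id),
           intrinsicId = "1",
           path = v$name,
           width = as.character(intr$image_width_px),
           height = as.character(intr$image_height_px))
    }),
    intrinsics = list(list(
      intrinsicId = "1",
      width = as.character(intr$image_width_px),
      height = as.character(intr$image_height_px),
      sensorWidth = fmt_num(intr$sensor_width_mm),
      sensorHeight = fmt_num(intr$sensor_width_mm *
                               intr$image_height_px / intr$image_width_px),
      serialNumber = intr$serial,
      type = "pinhole",
      pxFocalLength = fmt_num(focal_px),
      focalLength = fmt_num(intr$focal_length_mm),
      principalPoint = c(fmt_num(intr$image_width_px / 2),
                         fmt_num(intr$image_height_px / 2)),
      make = intr$make,
      model = intr$model
    )),
    poses = lapply(seq_along(scene$poses), function(i) {
      p <- scene$poses[[i]]
      list(poseId = as.character(i),
           pose = list(transform = list(
             rotation = fmt_num(as.vector(t(p$rotation))),  # row-major
             center = fmt_num(p$centre)
           ), locked = "0"))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an .sfm scene file written by [write_sfm()]
#'
#' @param path .sfm path.
#' @return an `"sfm_scene"`.
#' @export
read_sfm <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  intr <- doc$intrinsics[[1L]]
  intrinsics <- camera_intrinsics(
    make = intr$make, model = intr$model, serial = intr$serialNumber,
    focal_length_mm = as.numeric(intr$focalLength),
    focal_length_35mm = 1,
    sensor_width_mm = as.numeric(intr$sensorWidth),
    image_width_px = as.integer(intr$width),
    image_height_px = as.integer(intr$height))
  ## 35mm-equivalent is not part of the dialect; mark as unknown
  intrinsics$focal_length_35mm <- NA_real_
  views <- do.call(rbind, lapply(doc$views, function(v)
    data.frame(name = v$path, view_id = as.integer(v$viewId),
               intrinsic_id = as.integer(v$intrinsicId),
               pose_id = as.integer(v$poseId))))
  poses <- lapply(doc$poses, function(p) {
    r <- as.numeric(unlist(p$pose$transform$rotation))
    ctr <- as.numeric(unlist(p$pose$transform$center))
    structure(list(rotation = matrix(r, 3, 3, byrow = TRUE), centre = ctr),
              class = "camera_pose")
  })
  structure(list(views = views, intrinsics = intrinsics, poses = poses),
            class = "sfm_scene")
}
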