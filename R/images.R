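#' Read an image file
#'
#' Reads a PNG or TIFF image into a numeric array with intensities in
#' \[0, 1\]. The source bit depth (8 or 16) is recorded in the `"bitdepth"`
#' attribute so that writers can preserve it.
#'
#' @param path file path; format chosen from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix (grey) or H x W x C array with values in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  ## heuristics: readPNG/readTIFF rescale to [0,1]; assume 8-bit unless the
  ## quantisation grid clearly requires 16
  vals <- img[seq_len(min(length(img), 4096L))]
  depth <- if (any(abs(vals * 255 - round(vals * 255)) > 1e-6)) 16L else 8L
  attr(img, "bitdepth") <- depth
  img
}

#' Write an image file
#'
#' Writes a numeric array with values in \[0, 1\] as PNG or TIFF. TIFF output
#' honours the `"bitdepth"` attribute (8 or 16 bits per sample); PNG output
#' is 8-bit (16-bit images destined for PNG are quantized).
#'
#' @param img numeric matrix/array in \[0, 1\].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  depth <- attr(img, "bitdepth") %||% 8L
  switch(ext,
    png = png::writePNG(unclass_img(img), path),
    tif = ,
    tiff = tiff::writeTIFF(unclass_img(img), path, bits.per.sample = depth),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

unclass_img <- function(img) {
  attributes(img) <- attributes(img)[c("dim")]
  img
}

n_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3L] else 1L

#' Project an RGB image to a single grey channel
#'
#' Two projectors are available: plain channel averaging (the default used
#' for sharpness analysis throughout the package) and CIE 1976 L* lightness
#' computed from linearized sRGB, which emphasises small contrast variations
#' in highlights and shadows. The L* result is rescaled from \[0, 100\] to
#' the \[0, 1\] intensity range.
#'
#' @param image numeric array; H x W x 3 (an alpha channel, if present, is
#'   ignored), or an already-grey matrix (returned unchanged).
#' @param mode `"average"` or `"l_star"`.
#' @return numeric H x W matrix in \[0, 1\].
#' @export
grey_project <- function(image, mode = c("average", "l_star")) {
  mode <- match.arg(mode)
  if (is.matrix(image)) return(image)
  nd <- dim(image)
  if (length(nd) != 3L || !nd[3L] %in% c(3L, 4L))
    stop("grey_project: expected a 3-channel image, got ", nd[3L], " channels")
  r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
  if (mode == "average") {
    out <- (r + g + b) / 3
  } else {
    lin <- function(v) ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
    y <- 0.2126 * lin(r) + 0.7152 * lin(g) + 0.0722 * lin(b)
    d <- (6 / 29)^3
    fy <- ifelse(y > d, y^(1 / 3), y / (3 * (6 / 29)^2) + 4 / 29)
    out <- (116 * fy - 16) / 100
  }
  matrix(out, nd[1L], nd[2L])
}

#' Construct a focal stack
#'
#' An ordered set of images of one perspective captured at successive focal
#' plane positions. Index 0 is the most distal focal plane (camera farthest
#' from the specimen); successive planes have strictly increasing z indices.
#'
#' @param images list of numeric matrices/arrays, all with identical
#'   dimensions and channel counts.
#' @param z_indices integer vector, strictly increasing, one per image;
#'   default `0:(n-1)`.
#' @param perspective_id numeric length-2 vector `(x_angle_deg, y_angle_deg)`
#'   identifying the viewing perspective.
#' @return an object of class `"image_stack"`.
#' @export
image_stack <- function(images, z_indices = NULL,
                        perspective_id = c(0, 0)) {
  stopifnot(is.list(images), length(images) >= 1L)
  z_indices <- as.integer(z_indices %||% (seq_along(images) - 1L))
  if (length(z_indices) != length(images))
    stop("image_stack: one z index per image required")
  if (any(diff(z_indices) <= 0L))
    stop("image_stack: z_indices must be strictly increasing")
  d0 <- dim(images[[1L]])
  ok <- vapply(images, function(im) identical(dim(im), d0), logical(1L))
  if (!all(ok)) stop("image_stack: all images must share dimensions")
  structure(list(images = images, z_indices = z_indices,
                 perspective_id = perspective_id),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$images)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<image_stack> %d planes, %d x %d px, %d channel(s), z = [%s]\n",
              length(x$images), d[1L], d[2L],
              if (length(d) == 3L) d[3L] else 1L,
              paste(x$z_indices, collapse = ", ")))
  invisible(x)
}

#' Read a focal stack from a directory
#'
#' Images are read in lexicographic filename order. If filenames contain a
#' `_z<digits>` token the z index is taken from it, otherwise indices
#' `0:(n-1)` are assigned in sorted order.
#'
#' @param dir directory containing PNG/TIFF images of one perspective.
#' @param pattern filename filter (regular expression).
#' @param perspective_id see [image_stack()].
#' @return an `"image_stack"` with a `"filenames"` attribute.
#' @export
read_stack_dir <- function(dir, pattern = "\\.(png|tif|tiff)$",
                           perspective_id = c(0, 0)) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("read_stack_dir: no images found in ", dir)
  imgs <- lapply(files, read_image)
  zm <- regmatches(basename(files), regexpr("_z([0-9]+)", basename(files)))
  z <- if (length(zm) == length(files))
    as.integer(sub("_z", "", zm)) else seq_along(files) - 1L
  o <- order(z)
  st <- image_stack(imgs[o], z[o], perspective_id)
  attr(st, "filenames") <- basename(files)[o]
  st
}
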