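#' Masking parameters
#'
#' Tunables for the five-step background-removal routine. Defaults follow
#' the pipeline's standard operating point: a 5x5 Gaussian denoise, a 5x5
#' median filter, CLAHE with clip limit 2 on 64 px tiles, local-mean
#' adaptive thresholding over a 101 px block with an offset of -5 intensity
#' levels (8-bit scale), and a minimum component size of 1e-4 of the image
#' area (which operationalizes a cleanup threshold "determined by the image
#' resolution").
#'
#' @param gaussian_kernel odd Gaussian kernel size, px (>= 3).
#' @param median_kernel odd median kernel size, px (>= 3).
#' @param clahe_clip CLAHE clip limit (> 0).
#' @param clahe_tile CLAHE tile size, px.
#' @param adaptive_block odd local-mean block for infill removal, px.
#' @param adaptive_offset offset in 8-bit intensity levels; with the
#'   OpenCV-style sign convention a pixel inside the current foreground is
#'   background-like iff its grey value exceeds
#'   `local mean - adaptive_offset/255`.
#' @param min_component_fraction components (and holes) smaller than this
#'   fraction of the pixel count are removed (filled); must lie in
#'   (0, 0.01).
#' @param edge_threshold binarization threshold on the \[0, 1\] edge map.
#' @param closing_radius morphological closing radius (px) used to close
#'   small gaps in the thresholded edge map before filling.
#' @return an object of class `"mask_params"`.
#' @export
mask_params <- function(gaussian_kernel = 5L, median_kernel = 5L,
                        clahe_clip = 2, clahe_tile = 64L,
                        adaptive_block = 101L, adaptive_offset = -5,
                        min_component_fraction = 1e-4,
                        edge_threshold = 0.2, closing_radius = 3L) {
  stopifnot(is_odd(gaussian_kernel), gaussian_kernel >= 3L,
            is_odd(median_kernel), median_kernel >= 3L,
            clahe_clip > 0, clahe_tile >= 2L,
            is_odd(adaptive_block), adaptive_block >= 3L,
            min_component_fraction > 0, min_component_fraction < 0.01,
            edge_threshold > 0, edge_threshold < 1, closing_radius >= 1L)
  structure(list(gaussian_kernel = as.integer(gaussian_kernel),
                 median_kernel = as.integer(median_kernel),
                 clahe_clip = clahe_clip, clahe_tile = as.integer(clahe_tile),
                 adaptive_block = as.integer(adaptive_block),
                 adaptive_offset = adaptive_offset,
                 min_component_fraction = min_component_fraction,
                 edge_threshold = edge_threshold,
                 closing_radius = as.integer(closing_radius)),
            class = "mask_params")
}

## connected components with explicit connectivity (8 for foreground,
## 4 for background, the standard duality)
label_components <- function(mask, connectivity = 8L) {
  ccl_label(mask, as.integer(connectivity))
}

## fill background components not touching the image border (hole filling)
fill_holes <- function(mask) {
  lab <- label_components(!mask, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- mask
  hole[lab > 0L & !(lab %in% border)] <- TRUE
  hole
}

#' Denoise and contrast-enhance an EDOF image for edge detection
#'
#' Grey projection, Gaussian blur, median blur, then Contrast Limited
#' Adaptive Histogram Equalisation (CLAHE). The blurs suppress sensor noise
#' that edge detectors amplify; CLAHE lifts faint specimen-background
#' contrast without blowing out highlights. Constant images pass through
#' unchanged.
#'
#' @param edof numeric EDOF image (grey matrix or RGB array, \[0, 1\]).
#' @param params a [mask_params()] object.
#' @return numeric grey matrix in \[0, 1\], same height/width as the input.
#' @export
enhance <- function(edof, params = mask_params()) {
  g <- grey_project(edof, "average")
  sigma <- 0.3 * ((params$gaussian_kernel - 1) / 2 - 1) + 0.8
  g <- gaussian_blur(g, sigma, params$gaussian_kernel)
  g <- EBImage::medianFilter(pmin(pmax(g, 0), 1),
                             size = (params$median_kernel - 1L) %/% 2L)
  g <- as.matrix(g)
  if (diff(range(g)) < 1e-12) return(g)  # CLAHE is undefined on constants
  nx <- max(2L, round(ncol(g) / params$clahe_tile))
  ny <- max(2L, round(nrow(g) / params$clahe_tile))
  ## CLAHE needs dimensions divisible by the tile grid: replicate-pad out to
  ## the next multiple, equalize, crop back
  h <- nrow(g); w <- ncol(g)
  hp <- as.integer(ceiling(h / ny) * ny); wp <- as.integer(ceiling(w / nx) * nx)
  gp <- g[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
          drop = FALSE]
  ## EBImage uses x = columns for the first dimension
  e <- EBImage::clahe(EBImage::Image(t(gp)), nx = nx, ny = ny,
                      limit = params$clahe_clip, keep.range = FALSE)
  t(as.matrix(EBImage::imageData(e)))[seq_len(h), seq_len(w), drop = FALSE]
}

#' Detect specimen outlines in an enhanced image
#'
#' Returns a per-pixel boundary probability in \[0, 1\]. The self-contained
#' `"gradient"` detector is the normalized magnitude of the 3x3 Scharr
#' gradient of the enhanced image. The `"forest"` detector (a pre-trained
#' structured random forest) requires an external model file and inference
#' runtime that this package does not bundle; requesting it raises an
#' explicit configuration error rather than silently falling back.
#'
#' @param enhanced grey matrix from [enhance()].
#' @param detector `"gradient"` or `"forest"`.
#' @param model_path path to a structured-forest model (forest detector).
#' @return numeric matrix in \[0, 1\]; higher values mark likely boundaries.
#' @export
detect_outline <- function(enhanced, detector = c("gradient", "forest"),
                           model_path = NULL) {
  detector <- match.arg(detector)
  if (detector == "forest") {
    if (is.null(model_path) || !file.exists(model_path))
      stop("detect_outline: detector 'forest' requires a structured-forest ",
           "model file (model_path); none was found. No fallback is applied.")
    stop("detect_outline: structured-forest inference is not bundled with ",
         "this package; use detector = 'gradient'.")
  }
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 32
  p <- pad_replicate(enhanced, 1L)
  n <- nrow(enhanced); m <- ncol(enhanced)
  i <- 2:(n + 1); j <- 2:(m + 1)
  conv3 <- function(k) {
    out <- matrix(0, n, m)
    for (a in -1:1) for (b in -1:1)
      out <- out + k[a + 2, b + 2] * p[i + a, j + b]
    out
  }
  gy <- conv3(kx)       # vertical gradient (rows)
  gx <- conv3(t(kx))    # horizontal gradient (columns)
  mag <- sqrt(gx^2 + gy^2)
  ## normalize by the peak gradient, floored so that near-featureless images
  ## (e.g. bare background with a vignette) do not get their noise amplified
  ## into spurious "edges"
  pmin(mag / max(max(mag), 0.05), 1)
}

#' Extract the largest closed shape from an edge map
#'
#' Binarizes the edge map, closes small contour gaps morphologically, fills
#' enclosed regions, and keeps the 8-connected foreground component of
#' largest area — the specimen. If nothing survives binarization an empty
#' mask is returned with a warning and its `"empty"` attribute set.
#'
#' @param edges edge-probability matrix in \[0, 1\] (see [detect_outline()]).
#' @param threshold binarization threshold in (0, 1).
#' @param params a [mask_params()] (for the closing radius).
#' @return logical specimen mask (`TRUE` = specimen).
#' @export
largest_shape_mask <- function(edges, threshold = 0.2,
                               params = mask_params()) {
  stopifnot(threshold > 0, threshold < 1)
  bw <- edges >= threshold
  if (!any(bw)) {
    warning("largest_shape_mask: no contour found; returning empty mask")
    return(structure(matrix(FALSE, nrow(edges), ncol(edges)), empty = TRUE))
  }
  brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(t(bw)), brush)
  closed <- t(as.matrix(EBImage::imageData(closed))) > 0.5
  filled <- fill_holes(closed)
  lab <- label_components(filled, 8L)
  if (max(lab) == 0L) {
    warning("largest_shape_mask: no closed contour found; returning empty mask")
    return(structure(matrix(FALSE, nrow(edges), ncol(edges)), empty = TRUE))
  }
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Remove enclosed background from a specimen mask
#'
#' Filled outlines retain background regions the specimen encloses (e.g.
#' the area between a leg and the body). These are removed with adaptive
#' local-mean thresholding of the grey EDOF image, akin to luminance
#' keying: inside the current foreground, a pixel brighter than its local
#' mean by more than the configured offset is background-like (the evenly
#' lit dome background is brighter than a neighbourhood pulled down by the
#' dark cuticle) and is flipped to background. Background pixels are never
#' flipped to foreground. Works well as long as the lighting of the image
#' centre is reasonably uniform.
#'
#' @param mask logical specimen mask.
#' @param edof the EDOF image the mask belongs to.
#' @param params a [mask_params()] (`adaptive_block`, `adaptive_offset`).
#' @return logical mask with enclosed background removed.
#' @export
remove_infill <- function(mask, edof, params = mask_params()) {
  g <- grey_project(edof, "average")
  if (!identical(dim(mask), dim(g)))
    stop("remove_infill: mask and EDOF image dimensions differ")
  local_mean <- box_mean(g, params$adaptive_block)
  bg_like <- g > local_mean - params$adaptive_offset / 255
  out <- mask
  out[mask & bg_like] <- FALSE
  out
}

#' Clean a binary mask with connected-component labelling
#'
#' Foreground components (8-connected) with area below
#' `min_component_fraction * H * W` are removed, except that the largest
#' foreground component is always retained; background components
#' (4-connected holes) below the same threshold are filled. Components of
#' exactly the threshold area are kept. Idempotent.
#'
#' @param mask logical mask.
#' @param params a [mask_params()].
#' @return cleaned logical mask.
#' @export
clean_mask <- function(mask, params = mask_params()) {
  min_area <- params$min_component_fraction * length(mask)
  lab <- label_components(mask, 8L)
  out <- mask
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_area)
    drop <- setdiff(drop, which.max(sizes))  # largest always survives
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  labb <- label_components(!out, 4L)
  if (max(labb) > 0L) {
    sizes <- tabulate(labb[labb > 0L])
    fill <- which(sizes < min_area)
    if (length(fill)) out[labb %in% fill] <- TRUE
  }
  out
}

#' Apply a binary mask to an EDOF image
#'
#' `"alpha"` mode returns the image with an extra alpha channel equal to the
#' mask; `"zero"` mode sets background pixels to zero. Foreground pixel
#' values are bit-identical to the input in both modes.
#'
#' @param edof numeric image (grey matrix or RGB array).
#' @param mask logical mask of matching height/width.
#' @param mode `"alpha"` or `"zero"`.
#' @return masked image; alpha mode adds one channel.
#' @export
apply_cutout <- function(edof, mask, mode = c("alpha", "zero")) {
  mode <- match.arg(mode)
  d <- dim(edof)
  if (!identical(dim(mask), d[1:2]))
    stop("apply_cutout: mask and image dimensions differ")
  m <- mask * 1
  if (mode == "zero") {
    out <- if (length(d) == 3L) edof * array(m, d) else edof * m
  } else {
    chans <- if (length(d) == 3L)
      lapply(seq_len(d[3L]), function(k) edof[, , k]) else list(edof)
    out <- array(unlist(c(chans, list(m))), c(d[1:2], length(chans) + 1L))
  }
  attr(out, "bitdepth") <- attr(edof, "bitdepth")
  out
}

#' Five-step automatic masking pipeline
#'
#' Composition of [enhance()], [detect_outline()], [largest_shape_mask()],
#' [remove_infill()] and [clean_mask()], followed by [apply_cutout()]:
#' (i) enhance contours, (ii) approximate the specimen outline, (iii) remove
#' superfluous infill, (iv) clean the binary mask, (v) apply it to the input
#' image. Deterministic: identical inputs and parameters give bit-identical
#' masks.
#'
#' @param edof the EDOF image to mask.
#' @param params a [mask_params()].
#' @param detector edge detector, see [detect_outline()].
#' @param mode cut-out mode, see [apply_cutout()].
#' @param model_path structured-forest model path (forest detector only).
#' @return list with `mask` (logical, `TRUE` = specimen), `cutout` (masked
#'   image) and `empty` (flag set when no specimen was found).
#' @export
mask_pipeline <- function(edof, params = mask_params(),
                          detector = "gradient", mode = "zero",
                          model_path = NULL) {
  enh <- enhance(edof, params)
  edges <- detect_outline(enh, detector, model_path)
  mask <- largest_shape_mask(edges, params$edge_threshold, params)
  empty <- isTRUE(attr(mask, "empty"))
  if (!empty) {
    mask <- remove_infill(mask, edof, params)
    mask <- clean_mask(mask, params)
  }
  cut <- apply_cutout(edof, mask, mode)
  list(mask = mask, cutout = cut, empty = empty)
}

#' Write a binary mask as an 8-bit PNG
#'
#' White (255) marks the specimen, black (0) the background.
#'
#' @param mask logical mask.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path (white = specimen).
#' @return logical mask matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img >= 0.5
}
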