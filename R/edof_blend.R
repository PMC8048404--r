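#' Local contrast (sharpness energy) map
#'
#' Per-pixel sharpness used to decide which focal plane supplies each output
#' pixel: the local variance of the 3x3 Laplacian response within a square
#' window. Sharp edges produce a strong, spatially varying Laplacian and
#' hence high local variance; defocused regions are near zero.
#'
#' @param image numeric grey matrix (RGB is projected with the
#'   channel-average projector first).
#' @param window odd window size in pixels, >= 3.
#' @return non-negative numeric matrix, same size as the input.
#' @export
local_contrast_map <- function(image, window = 7L) {
  stopifnot(window >= 3L, is_odd(window))
  g <- grey_project(image, "average")
  L <- laplacian_response(g)
  v <- box_mean(L * L, window) - box_mean(L, window)^2
  pmax(v, 0)
}

#' Fuse an aligned focal stack into one EDOF image (hard mask)
#'
#' Winner-takes-all blending: for every pixel, the focal plane with the
#' highest [local_contrast_map()] value wins and its pixel is copied
#' verbatim into the output (no averaging, which preserves detail and
#' avoids halos where focal planes overlap). Selection uses local contrast
#' only; luminance and saturation play no role. The raw per-pixel argmax is
#' smoothed with a majority (mode) filter to suppress salt-and-pepper plane
#' switching before pixels are copied, so the copied-verbatim property holds
#' for the returned index map.
#'
#' Ties in contrast are broken towards the lowest z index (the most distal
#' plane), which makes blending deterministic and means a stack of
#' identical images returns the first image exactly.
#'
#' @param stack an aligned, non-empty [image_stack()] (see [align_stack()]).
#' @param window odd window for the local contrast analysis (px).
#' @param grey_projector `"average"` or `"l_star"`; projector used for the
#'   contrast analysis only — colour is copied untouched from the winning
#'   plane.
#' @param smooth odd size of the majority filter applied to the selection
#'   map (1 disables smoothing).
#' @return list with `edof` (numeric image, same dimensions and bit depth as
#'   the stack, with a `"provenance"` attribute listing source filenames)
#'   and `index_map` (integer matrix of winning z indices).
#' @export
blend_hard_mask <- function(stack, window = 7L, grey_projector = "average",
                            smooth = 5L) {
  if (!inherits(stack, "image_stack") || length(stack) == 0L)
    stop("blend_hard_mask: non-empty image_stack required")
  n <- length(stack)
  d <- dim(stack$images[[1L]])
  h <- d[1L]; w <- d[2L]
  if (n == 1L) {
    idx <- matrix(stack$z_indices[1L], h, w)
    edof <- stack$images[[1L]]
    attr(edof, "provenance") <- attr(stack, "filenames")
    return(list(edof = edof, index_map = idx))
  }
  contrast <- vapply(stack$images, function(im)
    local_contrast_map(grey_project(im, grey_projector), window),
    matrix(0, h, w))
  cmat <- matrix(contrast, h * w, n)
  sel <- max.col(cmat, ties.method = "first")  # plane position, 1-based
  if (smooth > 1L) {
    stopifnot(is_odd(smooth))
    votes <- vapply(seq_len(n), function(j)
      as.vector(box_sum(matrix(as.numeric(sel == j), h, w), smooth)),
      numeric(h * w))
    sel <- max.col(votes, ties.method = "first")
  }
  edof <- if (length(d) == 3L) array(0, d) else matrix(0, h, w)
  for (j in seq_len(n)) {
    pick <- sel == j
    if (!any(pick)) next
    if (length(d) == 3L) {
      for (k in seq_len(d[3L])) {
        ch <- edof[, , k]; src <- stack$images[[j]][, , k]
        ch[pick] <- src[pick]; edof[, , k] <- ch
      }
    } else edof[pick] <- stack$images[[j]][pick]
  }
  attr(edof, "bitdepth") <- attr(stack$images[[1L]], "bitdepth")
  attr(edof, "provenance") <- attr(stack, "filenames")
  list(edof = edof,
       index_map = matrix(stack$z_indices[sel], h, w))
}

#' Peak signal-to-noise ratio between two images
#'
#' Measured on the \[0, 1\] intensity scale (peak = 1). Used to quantify how
#' close a blended EDOF image comes to a known all-in-focus ground truth.
#'
#' @param x,y numeric images of identical dimensions.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}
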