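#' Variance-of-Laplacian focus score
#'
#' Sharpness of an image, measured as the population variance of the
#' response of the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over all pixels. In-focus images contain
#' strong intensity second derivatives and score high; defocused images
#' score low. The convolution uses replicate padding, so the response has
#' the same size as the input. RGB input is first reduced with the
#' channel-average grey projector (consistent with EDOF blending).
#'
#' @param image numeric matrix (grey) or H x W x 3 array in \[0, 1\].
#' @return non-negative scalar focus score (intensity^2 units); 0 iff the
#'   Laplacian response is spatially constant (e.g. a constant image).
#' @export
variance_of_laplacian <- function(image) {
  if (length(image) == 0L) stop("variance_of_laplacian: empty image")
  g <- grey_project(image, "average")
  L <- laplacian_response(g)
  mean((L - mean(L))^2)
}

#' Discard stack images with no in-focus content
#'
#' Scores every plane with [variance_of_laplacian()] and retains the
#' sub-stack whose score is greater than or equal to `threshold` (ties at
#' the threshold are kept). Z order and pixel data are preserved. The
#' optimal threshold depends on noise, z step, aperture and magnification
#' and must be determined empirically per setup; the default 0 retains
#' everything.
#'
#' @param stack an [image_stack()].
#' @param threshold non-negative focus-score cutoff.
#' @param log_csv optional path; per-image scores and retention flags are
#'   written there as CSV (columns `filename`, `z_index`, `focus_score`,
#'   `retained`).
#' @return the retained `"image_stack"` (possibly empty, with a warning),
#'   with the score table in the `"focus_log"` attribute.
#' @export
select_focused <- function(stack, threshold = 0, log_csv = NULL) {
  stopifnot(inherits(stack, "image_stack"), threshold >= 0)
  scores <- vapply(stack$images, variance_of_laplacian, numeric(1L))
  keep <- scores >= threshold
  fn <- attr(stack, "filenames") %||% rep(NA_character_, length(scores))
  log <- data.frame(filename = fn, z_index = stack$z_indices,
                    focus_score = scores, retained = keep)
  if (!is.null(log_csv)) write.csv(log, log_csv, row.names = FALSE)
  if (any(!keep))
    sf_log("INFO", "discarded z planes: ",
           paste(stack$z_indices[!keep], collapse = ", "))
  if (!any(keep)) {
    warning("select_focused: no image reached the focus threshold")
    out <- structure(list(images = list(), z_indices = integer(0),
                          perspective_id = stack$perspective_id),
                     class = "image_stack")
  } else {
    out <- image_stack(stack$images[keep], stack$z_indices[keep],
                       stack$perspective_id)
    attr(out, "filenames") <- fn[keep]
  }
  attr(out, "focus_log") <- log
  out
}
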