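#' Similarity transform (isotropic scale + translation)
#'
#' The motion model used for stack registration. The capture rig translates
#' the camera along its optical axis only, so successive focal planes differ
#' by a magnification change plus small in-plane jitter; rotation and shear
#' are excluded by design. The transform maps reference coordinates to
#' moving-image coordinates about the image centre:
#' `x_moving = scale * (x_ref - centre) + centre + (tx, ty)`,
#' where `tx` is the column (x) offset and `ty` the row (y) offset in
#' pixels. The identity is `(1, 0, 0)`.
#'
#' @param scale positive isotropic scale factor.
#' @param tx,ty translation in pixels (x = columns, y = rows).
#' @param score registration confidence in \[0, 1\] (phase-correlation peak).
#' @param low_confidence flag set when the input carried no usable texture.
#' @return an object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(scale = 1, tx = 0, ty = 0, score = NA_real_,
                                 low_confidence = FALSE) {
  stopifnot(scale > 0)
  structure(list(scale = scale, tx = tx, ty = ty, score = score,
                 low_confidence = low_confidence),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.5f, t = (%.3f, %.3f) px, score %.3f%s\n",
              x$scale, x$tx, x$ty, x$score,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

## phase correlation: returns the shift d (dy, dx) such that
## moving(x) = reference(x - d), plus the correlation peak height.
## Subpixel refinement by separable parabolic fit around the peak.
phase_correlate <- function(reference, moving, window = TRUE) {
  n <- nrow(reference); m <- ncol(reference)
  if (window) {
    w <- outer(hann(n), hann(m))
    reference <- (reference - mean(reference)) * w
    moving <- (moving - mean(moving)) * w
  }
  FR <- fft(reference); FM <- fft(moving)
  cp <- FR * Conj(FM)
  a <- Mod(cp); a[a < 1e-15] <- 1e-15
  r <- Re(fft(cp / a, inverse = TRUE)) / (n * m)
  pk <- which(r == max(r))[1L]
  i0 <- (pk - 1L) %% n; j0 <- (pk - 1L) %/% n  # zero-based peak coords
  wrap <- function(v, N) ifelse(v > N / 2, v - N, v)
  sub <- function(idx, N, get) {
    cm <- get((idx - 1L) %% N); cc <- get(idx); cp_ <- get((idx + 1L) %% N)
    den <- 2 * (2 * cc - cm - cp_)
    if (abs(den) < 1e-12) 0 else (cp_ - cm) / den
  }
  di <- sub(i0, n, function(i) r[i + 1L, j0 + 1L])
  dj <- sub(j0, m, function(j) r[i0 + 1L, j + 1L])
  peak_i <- wrap(i0, n) + di
  peak_j <- wrap(j0, m) + dj
  ## correlation peaks at x = -d (mod N)
  list(dy = -peak_i, dx = -peak_j, peak = max(r))
}

hann <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

## resample img under the similarity model: out(x) = img(s*(x - c) + c + t)
## bilinear interpolation, out-of-frame samples replicate the nearest edge
warp_similarity <- function(img, scale = 1, tx = 0, ty = 0) {
  d <- dim(img)
  n <- d[1L]; m <- d[2L]
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  ys <- scale * (seq_len(n) - cy) + cy + ty
  xs <- scale * (seq_len(m) - cx) + cx + tx
  ys <- pmin(pmax(ys, 1), n); xs <- pmin(pmax(xs, 1), m)
  y0 <- pmin(floor(ys), n - 1L); x0 <- pmin(floor(xs), m - 1L)
  fy <- ys - y0; fx <- xs - x0
  Y0 <- matrix(y0, n, m); FY <- matrix(fy, n, m)
  X0 <- matrix(x0, n, m, byrow = TRUE); FX <- matrix(fx, n, m, byrow = TRUE)
  yv <- as.vector(Y0); xv <- as.vector(X0)
  interp_one <- function(ch) {
    v00 <- ch[cbind(yv, xv)]; v10 <- ch[cbind(yv + 1, xv)]
    v01 <- ch[cbind(yv, xv + 1)]; v11 <- ch[cbind(yv + 1, xv + 1)]
    out <- v00 * (1 - FY) * (1 - FX) + v10 * FY * (1 - FX) +
      v01 * (1 - FY) * FX + v11 * FY * FX
    matrix(out, n, m)
  }
  if (length(d) == 3L) {
    out <- array(0, d)
    for (k in seq_len(d[3L])) out[, , k] <- interp_one(img[, , k])
  } else out <- interp_one(img)
  attr(out, "bitdepth") <- attr(img, "bitdepth")
  out
}

## theta-averaged log-polar profile of the windowed magnitude spectrum;
## spatial scaling by s shifts the profile along log-radius by log(s)
logpolar_profile <- function(img, nr = 256L, ntheta = 64L) {
  n <- nrow(img); m <- ncol(img)
  w <- outer(hann(n), hann(m))
  mag <- log1p(Mod(fftshift2(fft((img - mean(img)) * w))))
  cy <- floor(n / 2) + 1; cx <- floor(m / 2) + 1
  rmax <- min(n, m) / 2 - 1; rmin <- 3
  u <- seq(log(rmin), log(rmax), length.out = nr)
  th <- seq(0, pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  rr <- exp(u)
  ys <- cy + outer(rr, sin(th)); xs <- cx + outer(rr, cos(th))
  ys <- pmin(pmax(ys, 1), n); xs <- pmin(pmax(xs, 1), m)
  y0 <- pmin(floor(ys), n - 1); x0 <- pmin(floor(xs), m - 1)
  fy <- ys - y0; fx <- xs - x0
  yv <- as.vector(y0); xv <- as.vector(x0)
  fy <- as.vector(fy); fx <- as.vector(fx)
  v <- mag[cbind(yv, xv)] * (1 - fy) * (1 - fx) +
    mag[cbind(yv + 1, xv)] * fy * (1 - fx) +
    mag[cbind(yv, xv + 1)] * (1 - fy) * fx +
    mag[cbind(yv + 1, xv + 1)] * fy * fx
  prof <- rowMeans(matrix(v, length(rr), length(th)))
  list(profile = prof, du = diff(u[1:2]))
}

## 1-D phase correlation of log-radius profiles -> log-scale shift (in bins)
profile_shift <- function(a, b) {
  n <- length(a)
  w <- hann(n)
  A <- fft((a - mean(a)) * w); B <- fft((b - mean(b)) * w)
  cp <- A * Conj(B); mod <- Mod(cp); mod[mod < 1e-15] <- 1e-15
  r <- Re(fft(cp / mod, inverse = TRUE)) / n
  i0 <- which.max(r) - 1L
  cm <- r[(i0 - 1L) %% n + 1L]; cc <- r[i0 + 1L]; cp_ <- r[(i0 + 1L) %% n + 1L]
  den <- 2 * (2 * cc - cm - cp_)
  d <- i0 + if (abs(den) < 1e-12) 0 else (cp_ - cm) / den
  if (d > n / 2) d <- d - n
  -d
}

#' Register one image to a reference with a scale + translation model
#'
#' Estimates the [similarity_transform()] mapping reference coordinates onto
#' the moving image. Scale is initialized from the shift of the log-polar
#' (theta-averaged) magnitude-spectrum profile, which is invariant to
#' translation, and refined by maximizing the phase-correlation peak over
#' scale; translation then follows from phase correlation of the rescaled
#' pair with parabolic sub-pixel refinement. Deterministic for fixed inputs.
#'
#' Featureless (constant) inputs cannot be registered; the identity is
#' returned with `low_confidence = TRUE` and score 0.
#'
#' @param reference,moving numeric grey matrices (RGB arrays are projected
#'   with the channel-average grey projector) of identical dimensions.
#' @param refine logical; refine the spectral scale estimate by direct
#'   peak-height optimization (recommended).
#' @return a `"similarity_transform"`.
#' @export
register_pair <- function(reference, moving, refine = TRUE) {
  reference <- grey_project(reference, "average")
  moving <- grey_project(moving, "average")
  stopifnot(identical(dim(reference), dim(moving)))
  if (sd(reference) < 1e-10 || sd(moving) < 1e-10) {
    sf_log("WARN", "register_pair: featureless image, returning identity")
    return(similarity_transform(1, 0, 0, score = 0, low_confidence = TRUE))
  }
  lp_r <- logpolar_profile(reference)
  lp_m <- logpolar_profile(moving)
  ## spatial magnification by s compresses the magnitude spectrum by 1/s,
  ## i.e. shifts the log-radius profile by -log(s)
  s0 <- exp(-profile_shift(lp_r$profile, lp_m$profile) * lp_r$du)
  ## clamp the spectral estimate to the plausible stack magnification range
  s0 <- min(max(s0, 0.8), 1.25)
  margin <- max(4L, round(min(dim(reference)) / 8))
  crop <- function(x) x[(margin + 1):(nrow(x) - margin),
                        (margin + 1):(ncol(x) - margin), drop = FALSE]
  ## image-domain correlation of the fully compensated pair, evaluated on a
  ## central crop so edge-replication artefacts do not bias the optimum
  fit_at <- function(s) {
    pc <- phase_correlate(reference, warp_similarity(moving, s, 0, 0))
    aligned <- warp_similarity(moving, s, s * pc$dx, s * pc$dy)
    list(obj = stats::cor(as.vector(crop(reference)), as.vector(crop(aligned))),
         tx = s * pc$dx, ty = s * pc$dy, peak = pc$peak)
  }
  if (refine) {
    opt <- optimize(function(s) fit_at(s)$obj,
                    interval = c(s0 * 0.96, s0 * 1.04),
                    maximum = TRUE, tol = 1e-6)
    s <- opt$maximum
  } else s <- s0
  fit <- fit_at(s)
  similarity_transform(scale = s, tx = fit$tx, ty = fit$ty, score = fit$peak)
}

#' Align a focal stack to its most distal plane
#'
#' The image at z index 0 (most distal focal plane, widest field of view) is
#' the reference and is returned unchanged. Because focus overlap between
#' distant planes is shallow, each plane is registered against its z
#' neighbour and the transforms are composed to the reference; every plane
#' is then resampled into the reference frame (bilinear interpolation,
#' out-of-frame pixels replicate the edge). Output dimensions and bit depth
#' equal the input's.
#'
#' @param stack an [image_stack()] (non-empty).
#' @param write_json optional path for a sidecar JSON recording per-image
#'   transforms (`filename`, `scale`, `tx`, `ty`, `score`).
#' @return list with elements `stack` (aligned `"image_stack"`) and
#'   `transforms` (list of `"similarity_transform"`, identity first).
#' @export
align_stack <- function(stack, write_json = NULL) {
  stopifnot(inherits(stack, "image_stack"), length(stack) >= 1L)
  n <- length(stack)
  transforms <- vector("list", n)
  transforms[[1L]] <- similarity_transform(1, 0, 0, score = 1)
  aligned <- stack$images
  S <- 1; Tx <- 0; Ty <- 0
  for (i in seq_len(n)[-1L]) {
    tr <- register_pair(stack$images[[i - 1L]], stack$images[[i]])
    ## compose neighbour transform onto the chain to the reference
    S_new <- tr$scale * S
    Tx <- tr$scale * Tx + tr$tx
    Ty <- tr$scale * Ty + tr$ty
    S <- S_new
    transforms[[i]] <- similarity_transform(S, Tx, Ty, score = tr$score,
                                            low_confidence = tr$low_confidence)
    aligned[[i]] <- warp_similarity(stack$images[[i]], S, Tx, Ty)
  }
  out <- image_stack(aligned, stack$z_indices, stack$perspective_id)
  attr(out, "filenames") <- attr(stack, "filenames")
  if (!is.null(write_json)) {
    fn <- attr(stack, "filenames") %||% rep(NA_character_, n)
    rec <- lapply(seq_len(n), function(i) {
      tr <- transforms[[i]]
      list(filename = fn[i], scale = tr$scale, tx = tr$tx, ty = tr$ty,
           score = tr$score)
    })
    jsonlite::write_json(rec, write_json, auto_unbox = TRUE, digits = NA)
  }
  list(stack = out, transforms = transforms)
}
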