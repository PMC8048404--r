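## Seeded synthetic fixtures with ground truth. Every generator is a pure
## function of its arguments (seed included): identical calls are
## bit-reproducible, and each generator returns its ground truth alongside
## the data, so tests never need stored binary fixtures or hardware.

## smooth pseudo-random texture in [lo, hi]
random_texture <- function(h, w, smooth_sigma = 2, lo = 0, hi = 1) {
  x <- matrix(rnorm(h * w), h, w)
  x <- gaussian_blur(x, smooth_sigma)
  r <- range(x)
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Generate a focal stack with known all-in-focus ground truth
#'
#' Emulates capture of one perspective: a textured specimen-like scene over
#' a light-grey background is rendered once as the all-in-focus ground
#' truth, then each focal plane blurs the regions whose sharp plane is
#' elsewhere with a Gaussian whose sigma grows linearly with the plane
#' offset (a simple stand-in for defocus). The image is split into
#' `n_planes` vertical bands; band `j` is sharp in plane `j`. Optional
#' per-plane magnification and jitter (the most distal plane has the widest
#' field of view) are recorded as ground-truth transforms.
#'
#' @param n_planes number of focal planes (>= 1).
#' @param size `(H, W)` in pixels.
#' @param blur_scale defocus sigma per plane of depth offset (px); 0 renders
#'   every plane equal to the ground truth.
#' @param scales,shifts_x,shifts_y optional numeric vectors (length
#'   `n_planes`) of per-plane ground-truth transforms in the convention of
#'   [similarity_transform()] (plane 1 must be the identity); defaults are
#'   identity for all planes.
#' @param noise_sd additive Gaussian pixel noise, fraction of the intensity
#'   range.
#' @param seed integer seed; same seed, same bits.
#' @return list with `stack` (an [image_stack()]), `ground_truth` (sharp
#'   image), `index_map` (matrix of the sharp plane per pixel, z indices)
#'   and `transforms` (list of ground-truth [similarity_transform()]).
#' @export
make_focal_stack <- function(n_planes = 3L, size = c(128L, 128L),
                             blur_scale = 2, scales = NULL,
                             shifts_x = NULL, shifts_y = NULL,
                             noise_sd = 0, seed = 1L) {
  stopifnot(n_planes >= 1L)
  h <- size[1L]; w <- size[2L]
  scales <- scales %||% rep(1, n_planes)
  shifts_x <- shifts_x %||% rep(0, n_planes)
  shifts_y <- shifts_y %||% rep(0, n_planes)
  stopifnot(length(scales) == n_planes, scales[1L] == 1,
            shifts_x[1L] == 0, shifts_y[1L] == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gt <- random_texture(h, w, smooth_sigma = 1.5, lo = 0.2, hi = 0.9)
  ## dark specimen-ish blob in the middle adds strong edges
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- ((yy - h / 2) / (h / 3))^2 + ((xx - w / 2) / (w / 3))^2 <= 1
  gt[blob] <- gt[blob] * 0.4
  band <- pmin(floor((xx - 1) / (w / n_planes)) + 1L, n_planes)
  index_map <- matrix(band - 1L, h, w)
  planes <- vector("list", n_planes)
  transforms <- vector("list", n_planes)
  for (j in seq_len(n_planes)) {
    img <- gt
    for (b in seq_len(n_planes)) {
      sig <- blur_scale * abs(j - b)
      if (sig > 0) {
        blurred <- gaussian_blur(gt, sig)
        img[band == b] <- blurred[band == b]
      }
    }
    if (scales[j] != 1 || shifts_x[j] != 0 || shifts_y[j] != 0) {
      ## features of plane j sit at x_j = s (x_ref - c) + c + t; render by
      ## sampling the reference frame at the inverse mapping
      img <- warp_similarity(img, 1 / scales[j],
                             -shifts_x[j] / scales[j],
                             -shifts_y[j] / scales[j])
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    planes[[j]] <- pmin(pmax(img, 0), 1)
    transforms[[j]] <- similarity_transform(scales[j], shifts_x[j],
                                            shifts_y[j], score = 1)
  }
  list(stack = image_stack(planes, seq_len(n_planes) - 1L),
       ground_truth = gt, index_map = index_map, transforms = transforms)
}

#' Generate a specimen-like EDOF image with ground-truth mask
#'
#' Renders an articulated dark body (two ellipses and a head) with thin
#' appendages and an enclosed background hole, on a near-uniform light-grey
#' background with mild radial vignetting — the situation the masking
#' pipeline is built for. The enclosed hole is background in the ground
#' truth. Foreground/background separation of zero produces no usable
#' fixture and is rejected.
#'
#' @param size `(H, W)` pixels.
#' @param fg_level,bg_level mean grey of specimen and background in \[0, 1\]
#'   (`bg_level - fg_level` must be non-zero).
#' @param vignette amplitude of the radial background shading.
#' @param texture_amp amplitude of the specimen's surface texture.
#' @param noise_sd additive Gaussian pixel noise (fraction of range).
#' @param seed integer seed.
#' @return list with `edof` (grey image), `mask` (ground-truth logical mask,
#'   `TRUE` = specimen) and `hole` (logical map of the enclosed background).
#' @export
make_specimen_edof <- function(size = c(400L, 400L), fg_level = 0.15,
                               bg_level = 0.80, vignette = 0.03,
                               texture_amp = 0.05, noise_sd = 0, seed = 1L) {
  if (abs(bg_level - fg_level) < 1e-9)
    stop("make_specimen_edof: zero foreground/background separation; fixture unusable")
  h <- size[1L]; w <- size[2L]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ell <- function(cy, cx, ry, rx, ang = 0) {
    ca <- cos(ang); sa <- sin(ang)
    u <- (yy - cy) * ca + (xx - cx) * sa
    v <- -(yy - cy) * sa + (xx - cx) * ca
    (u / ry)^2 + (v / rx)^2 <= 1
  }
  seg <- function(y1, x1, y2, x2, width) {
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy^2 + dx^2
    t <- pmin(pmax(((yy - y1) * dy + (xx - x1) * dx) / len2, 0), 1)
    d2 <- (yy - (y1 + t * dy))^2 + (xx - (x1 + t * dx))^2
    d2 <= (width / 2)^2
  }
  cy <- h * 0.5; cx <- w * 0.45
  body <- ell(cy, cx, h * 0.17, w * 0.26) |
    ell(cy, cx + w * 0.22, h * 0.12, w * 0.12) |        # thorax/head lobe
    ell(cy, cx - w * 0.28, h * 0.10, w * 0.08)          # abdomen tip
  legs <- seg(cy - h * 0.10, cx + w * 0.05, cy - h * 0.33, cx + w * 0.22, 5) |
    seg(cy + h * 0.10, cx + w * 0.05, cy + h * 0.33, cx + w * 0.22, 5) |
    seg(cy - h * 0.12, cx - w * 0.08, cy - h * 0.34, cx - w * 0.20, 5) |
    seg(cy + h * 0.12, cx - w * 0.08, cy + h * 0.34, cx - w * 0.20, 5) |
    seg(cy - h * 0.08, cx + w * 0.28, cy - h * 0.28, cx + w * 0.40, 4) |
    seg(cy + h * 0.08, cx + w * 0.28, cy + h * 0.28, cx + w * 0.40, 4)
  antenna <- seg(cy, cx + w * 0.33, cy - h * 0.05, cx + w * 0.46, 3)
  hole <- ell(cy, cx - w * 0.05, h * 0.045, w * 0.045)  # enclosed background
  mask <- (body | legs | antenna) & !hole
  ## background with mild radial vignette, darkest at the corners
  r2 <- ((yy - h / 2) / (h / 2))^2 + ((xx - w / 2) / (w / 2))^2
  img <- bg_level - vignette * r2 / 2
  tex <- random_texture(h, w, smooth_sigma = 1.2, lo = -texture_amp, hi = texture_amp)
  img[mask] <- fg_level + tex[mask]
  img <- gaussian_blur(img, 0.7)  # optical softness at the silhouette
  if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  img <- pmin(pmax(img, 0), 1)
  list(edof = img, mask = mask, hole = hole)
}

#' Generate a gauge-cube pair mesh with a known step
#'
#' Two square plates side by side at the given heights, each triangulated
#' from a regular vertex grid, optionally with i.i.d. vertical vertex noise
#' — the synthetic analogue of scanning certified gauge blocks in pairs to
#' measure reconstruction accuracy (nominal steps of 0.500, 0.100 and
#' 0.050 mm from 1.50/1.10/1.05 mm blocks against a 1.00 mm reference).
#'
#' @param heights length-2 numeric: step-cube and reference-cube plate
#'   heights, mm.
#' @param noise_sd sd of vertical vertex noise, mm.
#' @param n_vertices approximate vertex count per plate.
#' @param seed integer seed.
#' @return list with `mesh` (a [tri_mesh()]), `top`/`reference`
#'   ([region_spec()] selectors for the two plates) and `true_step` (mm).
#' @export
make_step_cubes <- function(heights = c(1.50, 1.00), noise_sd = 0,
                            n_vertices = 400L, seed = 1L) {
  stopifnot(length(heights) == 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- max(2L, round(sqrt(n_vertices)))
  plate <- function(x0, height) {
    g <- expand.grid(x = seq(x0, x0 + 9, length.out = k),
                     y = seq(0, 9, length.out = k))
    z <- height + if (noise_sd > 0) rnorm(nrow(g), 0, noise_sd) else 0
    v <- cbind(g$x, g$y, z)
    ## grid triangulation
    idx <- matrix(seq_len(k * k), k, k)
    a <- as.vector(idx[-k, -k]); b <- as.vector(idx[-1, -k])
    cc <- as.vector(idx[-k, -1]); d <- as.vector(idx[-1, -1])
    f <- rbind(cbind(a, b, d), cbind(a, d, cc))
    list(v = v, f = f)
  }
  p1 <- plate(0, heights[1L])
  p2 <- plate(12, heights[2L])
  mesh <- tri_mesh(rbind(p1$v, p2$v), rbind(p1$f, p2$f + nrow(p1$v)))
  big <- max(abs(heights)) + 10 * max(noise_sd, 1)
  list(mesh = mesh,
       top = region_spec(c(-1, -1, -big), c(10, 10, big)),
       reference = region_spec(c(11, -1, -big), c(22, 10, big)),
       true_step = heights[1L] - heights[2L])
}

#' Generate raw samples with specified coefficients of variation
#'
#' Normal samples with `sd = true_cv * mean` per group, for simulation
#' studies of CV-equality tests (type-I error under equal CVs, power under
#' unequal CVs).
#'
#' @param k number of groups.
#' @param n observations per group (scalar or length-k).
#' @param true_cvs length-k coefficients of variation.
#' @param means length-k group means (scalar recycled).
#' @param seed integer seed.
#' @return list of `k` numeric vectors.
#' @export
make_cv_groups <- function(k, n, true_cvs, means = 1, seed = 1L) {
  n <- rep_len(n, k); true_cvs <- rep_len(true_cvs, k)
  means <- rep_len(means, k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(k), function(i)
    rnorm(n[i], means[i], true_cvs[i] * means[i]))
}

#' Generate an icosphere mesh
#'
#' Subdivided icosahedron projected onto the sphere — the standard
#' refinement fixture whose area and volume converge to the closed forms
#' `4*pi*r^2` and `4/3*pi*r^3`.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @return a watertight [tri_mesh()].
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  normalize <- function(m) m / sqrt(rowSums(m^2)) * radius
  v <- normalize(v)
  for (s in seq_len(subdivisions)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                          cbind(f[, 3], f[, 1])))
    ek <- key(edges[, 1], edges[, 2])
    dup <- duplicated(ek)
    edges <- edges[!dup, , drop = FALSE]; ek <- ek[!dup]
    mids <- normalize((v[edges[, 1], , drop = FALSE] +
                         v[edges[, 2], , drop = FALSE]) / 2)
    mid_id <- stats::setNames(nrow(v) + seq_len(nrow(mids)), ek)
    v <- rbind(v, mids)
    m12 <- mid_id[key(f[, 1], f[, 2])]
    m23 <- mid_id[key(f[, 2], f[, 3])]
    m31 <- mid_id[key(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  tri_mesh(v, f)
}

## save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
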