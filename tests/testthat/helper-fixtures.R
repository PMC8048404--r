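options(scanforge.quiet = TRUE)

iou <- function(a, b) sum(a & b) / sum(a | b)

## watertight unit cube (12 triangles, consistently outward-wound)
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0
             c(5, 6, 8), c(5, 8, 7),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = 1
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = 1
  tri_mesh(v, f)
}

## seeded textured image for registration fixtures
textured_image <- function(n = 128L, seed = 42L) {
  set.seed(seed)
  scanforge:::random_texture(n, n, smooth_sigma = 1.5)
}

## centred disk/annulus grey images for masking fixtures
radial_dist <- function(h, w, cy = (h + 1) / 2, cx = (w + 1) / 2) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((yy - cy)^2 + (xx - cx)^2)
}
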