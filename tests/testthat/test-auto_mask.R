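test_that("enhance denoises and raises global contrast", {
  # constants pass through (blurs and CLAHE preserve them)
  flat <- matrix(0.6, 80, 80)
  expect_equal(enhance(flat), flat, tolerance = 1e-8)

  # CLAHE lifts the p99 - p1 spread of a low-contrast fixture
  set.seed(31)
  lc <- scanforge:::random_texture(200, 200, 3, lo = 0.45, hi = 0.55)
  spread <- function(x) diff(quantile(x, c(0.01, 0.99)))
  expect_gt(spread(enhance(lc)), spread(lc))

  # the median step removes isolated salt-and-pepper corruption
  set.seed(32)
  img <- matrix(0.5, 200, 200)
  idx <- sample(length(img), 400)
  img[idx] <- rep(c(0, 1), 200)
  med <- as.matrix(EBImage::medianFilter(img, 2))
  expect_gte(mean(abs(med[idx] - 0.5) < 0.01), 0.99)
})

test_that("gradient edge detector localizes object boundaries", {
  expect_true(all(detect_outline(matrix(0.5, 50, 50)) == 0))

  # filled disk: edge mass concentrated in a thin annulus on the boundary
  r <- radial_dist(200, 200)
  disk <- ifelse(r <= 50, 0.2, 0.8)
  ed <- detect_outline(enhance(disk))
  expect_true(all(ed >= 0 & ed <= 1))
  expect_gte(sum(ed[abs(r - 50) <= 4]) / sum(ed), 0.9)

  # nested contours: both ring boundaries respond
  ring <- ifelse(r <= 60 & r >= 40, 0.15, 0.8)
  edr <- detect_outline(enhance(ring))
  expect_gt(mean(edr[abs(r - 60) <= 3]), 10 * mean(edr[r < 30 | r > 75]))
  expect_gt(mean(edr[abs(r - 40) <= 3]), 10 * mean(edr[r < 30 | r > 75]))
})

test_that("forest detector demands its model file explicitly", {
  expect_error(detect_outline(matrix(0.5, 10, 10), "forest"), "model file")
  f <- withr::local_tempfile(fileext = ".yml"); writeLines("stub", f)
  expect_error(detect_outline(matrix(0.5, 10, 10), "forest", f), "not bundled")
})

test_that("largest_shape_mask keeps only the biggest closed shape", {
  r1 <- radial_dist(200, 200, cy = 100, cx = 60)
  r2 <- radial_dist(200, 200, cy = 100, cx = 160)
  two <- ifelse(r1 <= 40 | r2 <= 15, 0.15, 0.8)
  edges <- detect_outline(enhance(two))
  mask <- largest_shape_mask(edges, 0.2)
  expect_gte(mean(mask[r1 <= 38]), 0.99)   # big disk kept
  expect_equal(sum(mask[r2 <= 13]), 0)     # small disk dropped

  expect_warning(empty <- largest_shape_mask(matrix(0, 50, 50) + 1e-9, 0.5),
                 "no contour")
  expect_true(isTRUE(attr(empty, "empty")))
  expect_false(any(empty))
})

test_that("remove_infill flips enclosed background but preserves solids", {
  r <- radial_dist(200, 200)
  # dark ring enclosing dome-grey background
  ring_img <- ifelse(r <= 50 & r >= 30, 0.15, 0.8)
  filled <- r <= 50
  out <- remove_infill(filled, ring_img)
  expect_true(all(!out[r < 28]))                 # enclosed disc flipped
  expect_true(all(out[r <= 48 & r >= 32]))       # ring retained

  # solid specimen without holes: essentially unchanged
  solid_img <- ifelse(r <= 50, 0.15, 0.8)
  solid <- r <= 50
  expect_lte(mean(remove_infill(solid, solid_img) != solid), 0.001)

  # all-background mask untouched; never flips background to foreground
  none <- matrix(FALSE, 200, 200)
  expect_identical(remove_infill(none, ring_img), none)
})

test_that("clean_mask removes speckle, fills pinholes, keeps the threshold tie", {
  # 10 speckles of 4 px + one 10,000 px component on a 1000 x 1000 canvas:
  # min area is 1e-4 * 1e6 = 100 px, so exactly one component survives
  m <- matrix(FALSE, 1000, 1000)
  m[100:199, 100:199] <- TRUE
  set.seed(5)
  for (k in 1:10) {
    i <- sample(500:900, 1); j <- sample(500:900, 1)
    m[i:(i + 1), j:(j + 1)] <- TRUE
  }
  mc <- clean_mask(m)
  expect_equal(max(scanforge:::label_components(mc, 8)), 1)

  # a component of exactly the threshold area is retained (>= rule)
  m2 <- matrix(FALSE, 100, 100)          # min area = 1 px at 1e-4
  m2[4, 7] <- TRUE
  m2[40:80, 40:80] <- TRUE
  expect_true(clean_mask(m2)[4, 7])

  # idempotence and stability of an already-clean mask
  expect_identical(clean_mask(mc), mc)
  single <- matrix(FALSE, 120, 120); single[30:90, 30:90] <- TRUE
  expect_identical(clean_mask(single), single)
})

test_that("cut-outs zero the background or add an alpha channel, bit-exactly", {
  fx <- make_specimen_edof(size = c(150, 150), seed = 3)
  mask <- fx$mask
  z <- apply_cutout(fx$edof, mask, "zero")
  expect_identical(z[mask], fx$edof[mask])
  expect_true(all(z[!mask] == 0))
  a <- apply_cutout(fx$edof, mask, "alpha")
  expect_equal(dim(a), c(150, 150, 2))
  expect_identical(a[, , 1][mask], fx$edof[mask])
  expect_identical(a[, , 2], mask * 1)

  full <- matrix(TRUE, 150, 150)
  expect_identical(apply_cutout(fx$edof, full, "zero")[, ], fx$edof[, ])
  none <- matrix(FALSE, 150, 150)
  expect_true(all(apply_cutout(fx$edof, none, "zero") == 0))
  expect_error(apply_cutout(fx$edof, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("mask pipeline recovers the synthetic specimen mask", {
  fx <- make_specimen_edof(seed = 1)
  res <- mask_pipeline(fx$edof)
  expect_gte(iou(res$mask, fx$mask), 0.95)
  expect_true(all(!res$mask[fx$hole]))           # enclosed background removed
  expect_identical(res$cutout[res$mask], fx$edof[res$mask])  # fg untouched

  noisy <- make_specimen_edof(noise_sd = 0.02, seed = 1)
  expect_gte(iou(mask_pipeline(noisy$edof)$mask, noisy$mask), 0.93)
})

test_that("mask quality degrades monotonically with noise", {
  ious <- vapply(c(0, 0.02, 0.05), function(ns) {
    fx <- make_specimen_edof(noise_sd = ns, seed = 1)
    iou(mask_pipeline(fx$edof)$mask, fx$mask)
  }, numeric(1))
  expect_true(all(diff(ious) <= 0))
})

test_that("masking is deterministic and empty on background-only images", {
  fx <- make_specimen_edof(seed = 2)
  r1 <- mask_pipeline(fx$edof)
  r2 <- mask_pipeline(fx$edof)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$cutout, r2$cutout)

  bg <- matrix(0.8, 300, 300) -
    0.015 * ((matrix(1:300, 300, 300) - 150) / 150)^2
  expect_warning(res <- mask_pipeline(bg), "no contour")
  expect_true(res$empty)
  expect_false(any(res$mask))
  expect_true(all(res$cutout == 0))
})

test_that("mask PNG round-trips as a binary white-foreground image", {
  fx <- make_specimen_edof(size = c(120, 120), seed = 4)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(fx$mask, f)
  expect_identical(read_mask(f), fx$mask)
  raw_png <- png::readPNG(f)
  expect_true(all(raw_png %in% c(0, 1)))
})

test_that("connected components honour the 8/4 connectivity duality", {
  # two diagonal pixels: one 8-connected component, two 4-connected ones
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(scanforge:::label_components(m, 8)), 1)
  expect_equal(max(scanforge:::label_components(m, 4)), 2)
})
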