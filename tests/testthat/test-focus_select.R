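test_that("variance of Laplacian matches hand-convolved closed forms", {
  # constant image: Laplacian response is identically zero
  expect_identical(variance_of_laplacian(matrix(0.7, 12, 9)), 0)
  expect_identical(variance_of_laplacian(matrix(0, 5, 5)), 0)

  # centred impulse of amplitude a on an N x N zero image: response is -4a at
  # the centre and +a at the 4 neighbours, mean 0, so variance = 20 a^2 / N^2
  for (case in list(list(N = 9, a = 1), list(N = 15, a = 0.5),
                    list(N = 7, a = 2))) {
    img <- matrix(0, case$N, case$N)
    ctr <- (case$N + 1) / 2
    img[ctr, ctr] <- case$a
    expect_equal(variance_of_laplacian(img), 20 * case$a^2 / case$N^2,
                 tolerance = 1e-12)
  }
})

test_that("focus score decreases under repeated Gaussian blurring", {
  img <- textured_image(100, seed = 21)
  # checkerboard-style sharp/blurred ordering
  sharp <- variance_of_laplacian(img)
  blurred <- variance_of_laplacian(scanforge:::gaussian_blur(img, 2))
  expect_gt(sharp, blurred)
  # strict decrease over >= 3 blur levels
  scores <- vapply(c(0.5, 1, 2, 4), function(s)
    variance_of_laplacian(scanforge:::gaussian_blur(img, s)), numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("variance_of_laplacian rejects empty input and accepts RGB", {
  expect_error(variance_of_laplacian(matrix(numeric(0), 0, 0)), "empty")
  rgb <- array(runif(48), c(4, 4, 3))
  grey <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  expect_equal(variance_of_laplacian(rgb), variance_of_laplacian(grey))
})

test_that("select_focused filters by threshold, preserving order and ties", {
  # constant stack: everything below any positive threshold
  const <- image_stack(replicate(5, matrix(0.4, 16, 16), simplify = FALSE))
  expect_warning(out <- select_focused(const, 0.1), "no image")
  expect_length(out, 0)

  # 10-plane stack, exactly 4 planes carry sharp content above threshold
  base <- textured_image(64, seed = 8)
  sharp_at <- c(2, 5, 6, 9)
  planes <- lapply(1:10, function(j)
    if (j %in% sharp_at) base else scanforge:::gaussian_blur(base, 6))
  st <- image_stack(planes)
  thr <- mean(c(variance_of_laplacian(base),
                variance_of_laplacian(scanforge:::gaussian_blur(base, 6))))
  kept <- select_focused(st, thr)
  expect_equal(kept$z_indices, sharp_at - 1L)

  # threshold 0 retains the full stack; ties at the threshold are retained
  expect_length(select_focused(st, 0), 10)
  s5 <- variance_of_laplacian(planes[[5]])
  expect_true(4L %in% select_focused(st, s5)$z_indices)
})

test_that("retention is a subsequence and monotone in the threshold", {
  st <- make_focal_stack(n_planes = 6, size = c(64, 64), blur_scale = 1.5,
                         seed = 4)$stack
  scores <- vapply(st$images, variance_of_laplacian, numeric(1))
  prev <- length(st)
  for (thr in quantile(scores, c(0, 0.3, 0.6, 1))) {
    kept <- suppressWarnings(select_focused(st, thr))
    expect_true(all(kept$z_indices %in% st$z_indices))
    expect_true(!is.unsorted(kept$z_indices))
    expect_lte(length(kept), prev)
    prev <- length(kept)
  }
})

test_that("select_focused writes a per-image score log", {
  st <- make_focal_stack(n_planes = 3, size = c(32, 32), seed = 2)$stack
  csv <- withr::local_tempfile(fileext = ".csv")
  kept <- select_focused(st, 0, log_csv = csv)
  log <- read.csv(csv)
  expect_named(log, c("filename", "z_index", "focus_score", "retained"))
  expect_equal(nrow(log), 3)
  expect_true(all(log$retained))
  expect_equal(attr(kept, "focus_log")$focus_score, log$focus_score)
})
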