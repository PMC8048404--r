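test_that("coefficients of variation match the published worked examples", {
  # femur length 2D/3D and abdomen length 2D/3D summary rows
  expect_equal(round(cv(6.25, 0.10), 3), 0.016)
  expect_equal(round(cv(6.57, 0.07), 3), 0.011)
  expect_equal(round(cv(18.15, 1.16), 3), 0.064)
  expect_equal(round(cv(19.59, 0.20), 3), 0.010)

  expect_equal(cv(group_summary(7, 6.25, 0.10)), 0.016)
  expect_equal(cv(5, 0), 0)
  expect_error(cv(0, 1), "zero")
  expect_error(group_summary(7, 0, 1), "zero")
})

test_that("the Feltz-Miller statistic equals the direct-formula oracle", {
  # frozen oracle: k = 2, n = (7, 7), CVs (0.02, 0.05);
  # m_i = 6, pooled c = 0.035, D = 12 * 0.015^2 / (0.035^2 * (0.5 + 0.035^2))
  fm <- feltz_miller_test(list(group_summary(7, 1, 0.02),
                               group_summary(7, 1, 0.05)))
  expect_equal(fm$statistic, 4.3973896606375602, tolerance = 1e-12)
  expect_equal(fm$df, 1L)
  expect_equal(fm$p.value, 0.035993983540459969, tolerance = 1e-12)
})

test_that("identical CVs give a null statistic and p = 1", {
  fm <- feltz_miller_test(list(group_summary(10, 2.0, 0.04),
                               group_summary(15, 5.0, 0.10)))
  expect_equal(fm$statistic, 0)
  expect_equal(fm$p.value, 1)
})

test_that("the statistic is invariant to relabelling and per-group rescaling", {
  g <- list(group_summary(7, 3.12, 0.04, "a"),
            group_summary(9, 6.25, 0.10, "b"),
            group_summary(12, 18.15, 1.16, "c"))
  base <- feltz_miller_test(g)$statistic
  expect_equal(feltz_miller_test(rev(g))$statistic, base, tolerance = 1e-12)
  scaled <- list(group_summary(7, 3.12 * 4, 0.04 * 4, "a"),
                 group_summary(9, 6.25, 0.10, "b"),
                 group_summary(12, 18.15 * 0.1, 1.16 * 0.1, "c"))
  expect_equal(feltz_miller_test(scaled)$statistic, base, tolerance = 1e-12)
  expect_equal(feltz_miller_test(g)$df, 2L)
})

test_that("the statistic is non-negative and p decreases as D grows", {
  set.seed(14)
  stats <- replicate(50, {
    s <- lapply(1:3, function(i)
      group_summary(sample(5:30, 1), runif(1, 1, 20), runif(1, 0.01, 2)))
    feltz_miller_test(s)$statistic
  })
  expect_true(all(stats >= 0))
  d <- sort(stats)
  p <- pchisq(d, 2, lower.tail = FALSE)
  expect_true(all(diff(p) <= 0))
})

test_that("data-frame input and raw-sample wrapper agree", {
  df <- data.frame(label = c("2D", "3D"), n = c(7, 7),
                   mean = c(3.12, 3.20), sd = c(0.04, 0.01))
  a <- feltz_miller_test(df)
  b <- feltz_miller_test(list(group_summary(7, 3.12, 0.04),
                              group_summary(7, 3.20, 0.01)))
  expect_equal(a$statistic, b$statistic)

  smp <- make_cv_groups(2, 30, c(0.05, 0.05), means = c(2, 8), seed = 3)
  fm <- feltz_miller_test_samples(smp)
  direct <- feltz_miller_test(lapply(smp, summarize_sample))
  expect_equal(fm$statistic, direct$statistic)
})

test_that("the test attains near-nominal size and full power asymptotically", {
  # moderate-n type-I check (the full 5000-replicate calibration runs in the
  # acceptance suite); here: power -> 1 for clearly unequal CVs at large n
  set.seed(99)
  rej <- replicate(200, {
    x <- rnorm(400, 1, 0.05); y <- rnorm(400, 1, 0.15)
    feltz_miller_test_samples(list(x, y))$p.value < 0.05
  })
  expect_gte(mean(rej), 0.99)
})

test_that("log-log OLS recovers a known scaling exponent", {
  set.seed(8)
  x <- 10^runif(40, 0, 3)
  y <- 3 * x^(2 / 3) * 10^rnorm(40, 0, 0.02)
  fit <- loglog_ols(x, y)
  expect_equal(fit$slope, 2 / 3, tolerance = 0.02)
  expect_true(fit$ci[1] < 2 / 3 && 2 / 3 < fit$ci[2])
})
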