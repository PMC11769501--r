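# Default-bandwidth constant used in several checks: at zero distance the
# multiscale kernel equals the sum of squared bandwidths,
# 0.2^2 + 0.5^2 + 0.9^2 + 1.3^2 + 1.5^2 + 1.6^2 = 7.60.
kernel_at_zero <- 0.04 + 0.25 + 0.81 + 1.69 + 2.25 + 2.56

test_that("the multiscale kernel is 7.60 at zero distance and decreasing", {
  expect_equal(multiscale_kernel(0), kernel_at_zero, tolerance = 1e-12)
  d <- c(0, 0.1, 1, 10, 100, 1e4, 1e8)
  k <- multiscale_kernel(d)
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-6)
  expect_error(multiscale_kernel(-1), "non-negative")
})

test_that("the biased squared MMD vanishes at equality and is symmetric", {
  set.seed(1)
  x <- matrix(rnorm(90), ncol = 3L)
  y <- matrix(rnorm(120, mean = 1), ncol = 3L)
  expect_equal(mmd_squared(x, x), 0, tolerance = 1e-12)
  expect_equal(mmd_squared(x, y), mmd_squared(y, x), tolerance = 1e-12)
  expect_error(mmd_squared(x, y[, 1:2]), "dimension mismatch")
})

test_that("far-separated clouds converge to the within-cloud kernel means", {
  set.seed(2)
  x <- matrix(rnorm(150), ncol = 3L)
  y <- matrix(rnorm(150), ncol = 3L) + 5000
  kxx <- multiscale_kernel(harshift:::.sq_dists(x, x))
  kyy <- multiscale_kernel(harshift:::.sq_dists(y, y))
  kxy <- multiscale_kernel(harshift:::.sq_dists(x, y))
  expect_lt(mean(kxy), 1e-6)
  expect_equal(mmd_squared(x, y), mean(kxx) + mean(kyy) - 2 * mean(kxy),
               tolerance = 1e-12)
})

test_that("the estimate grows monotonically with a mean shift", {
  deltas <- c(0, 0.5, 1, 2)
  means <- vapply(deltas, function(d) {
    mean(vapply(1:50, function(s) {
      set.seed(1000 + s)
      x <- matrix(rnorm(300), ncol = 3L)
      y <- matrix(rnorm(300, mean = d), ncol = 3L)
      mmd_squared(x, y)
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("every reported value of the biased estimator is non-negative", {
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rnorm(60 + 3 * i), ncol = 3L)
    y <- matrix(rnorm(90, sd = runif(1, 0.2, 3)), ncol = 3L)
    expect_gte(mmd_squared(x, y), 0)
  }
})

test_that("a single iteration equals a direct call on the seed-selected windows", {
  set.seed(4)
  a <- matrix(rnorm(600), ncol = 3L)
  b <- matrix(rnorm(900), ncol = 3L)
  cfg <- mmd_config(window_samples = 100L, iterations = 1L, seed = 17L)
  got <- iterative_mmd(a, b, cfg)
  na <- nrow(a) - 100L + 1L
  nb <- nrow(b) - 100L + 1L
  starts <- withr::with_seed(17L, {
    sa <- sample.int(na, 1L, replace = TRUE)
    sb <- sample.int(nb, 1L, replace = TRUE)
    c(sa, sb)
  })
  direct <- mmd_squared(a[starts[1L]:(starts[1L] + 99L), ],
                        b[starts[2L]:(starts[2L] + 99L), ], cfg)
  expect_equal(got$value, direct, tolerance = 1e-12)
  expect_identical(got$n_iterations, 1L)
})

test_that("a mean-shifted copy yields a larger iterative MMD than identity", {
  set.seed(5)
  a <- matrix(rnorm(3000), ncol = 3L)
  cfg <- mmd_config(iterations = 2000L, seed = 6L)
  same <- iterative_mmd(a, a, cfg)$value
  shifted <- iterative_mmd(a, a + 1, cfg)$value
  expect_lt(same, shifted)
})

test_that("disjoint seeds agree within three combined standard errors", {
  p <- make_cohort(1L, seed = 30L)[[1L]]
  rec <- simulate_session(p, harvar_sensors()["ER"], walk_min_per_speed = 0.2,
                          nonwalk_min = 0.1)$ER
  walk <- rec$samples[rec$labels == 1L, ]
  half <- nrow(walk) %/% 2L
  a <- walk[1:half, ]
  b <- walk[(half + 1L):nrow(walk), ]
  r1 <- iterative_mmd(a, b, mmd_config(iterations = 2000L, seed = 100L))
  r2 <- iterative_mmd(a, b, mmd_config(iterations = 2000L, seed = 200L))
  expect_lt(abs(r1$value - r2$value), 3 * sqrt(r1$se^2 + r2$se^2))
})

test_that("the Monte-Carlo estimator matches exhaustive enumeration", {
  set.seed(7)
  a <- matrix(rnorm(160 * 3), ncol = 3L)
  b <- matrix(rnorm(160 * 3, mean = 0.3), ncol = 3L)
  cfg <- mmd_config(iterations = 2000L, seed = 8L)
  exact <- enumerate_mmd(a, b, cfg)
  mc <- iterative_mmd(a, b, cfg)
  expect_lt(abs(mc$value - exact), 2 * mc$se)
})

test_that("iterative MMD is non-decreasing in rotation angle on walking data", {
  p <- make_cohort(1L, seed = 40L)[[1L]]
  zero_noise <- sensor_spec("Z0", "right", 0, 64, 0, "A")
  rec <- simulate_session(p, list(zero_noise), walk_min_per_speed = 0.15,
                          nonwalk_min = 0.1)[[1L]]
  walk <- rec$samples[rec$labels == 1L, ]
  angles <- c(0, 15, 30, 45, 60, 90)
  means <- vapply(angles, function(th) {
    rot <- rotate_signal(walk, th)
    mean(vapply(1:20, function(s) {
      iterative_mmd(walk, rot, mmd_config(iterations = 60L, seed = 500L + s))$value
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("series shorter than the window are rejected by name", {
  a <- matrix(rnorm(60), ncol = 3L)
  b <- matrix(rnorm(600), ncol = 3L)
  expect_error(iterative_mmd(a, b), "series_a")
  expect_error(iterative_mmd(b, a), "series_b")
})

test_that("per-class MMD restricts, averages, and flags missing classes", {
  set.seed(9)
  # binary walking task: only the walking class enters
  a <- matrix(rnorm(1200), ncol = 3L)
  la <- rep(c(0L, 1L), each = 200L)
  b <- matrix(rnorm(1200, mean = 0.5), ncol = 3L)
  cfg <- mmd_config(iterations = 50L, seed = 3L)
  res <- per_class_mmd(a, la, b, la, classes_to_use = 1L, config = cfg)
  expect_length(res$per_class, 1L)
  expect_identical(res$mean, unname(res$per_class))

  # many-class data: the mean is the arithmetic class average
  k <- 33L
  n_per <- 120L
  lab <- rep(seq_len(k), each = n_per)
  xa <- matrix(rnorm(k * n_per * 3), ncol = 3L)
  xb <- matrix(rnorm(k * n_per * 3, mean = 0.2), ncol = 3L)
  cfg2 <- mmd_config(iterations = 5L, seed = 4L)
  multi <- per_class_mmd(xa, lab, xb, lab, classes_to_use = seq_len(k),
                         config = cfg2)
  expect_equal(multi$mean, mean(multi$per_class), tolerance = 1e-12)
  expect_length(multi$per_class, k)

  # a class absent on one side is excluded with a warning
  lb <- lab
  lb[lb == 2L] <- 1L
  expect_warning(part <- per_class_mmd(xa, lab, xb, lb,
                                       classes_to_use = c(1L, 2L),
                                       config = cfg2),
                 "class 2")
  expect_true(is.na(part$per_class[["2"]]))
  expect_identical(part$mean, unname(part$per_class[["1"]]))
})

test_that("an identical pair scores below a rotated pair at the same seed", {
  p <- make_cohort(1L, seed = 50L)[[1L]]
  rec <- simulate_session(p, list(sensor_spec("Z0", "right", 0, 64, 0.01, "A")),
                          walk_min_per_speed = 0.1, nonwalk_min = 0.1)[[1L]]
  walk <- rec$samples[rec$labels == 1L, ]
  cfg <- mmd_config(iterations = 300L, seed = 11L)
  same <- iterative_mmd(walk, walk, cfg)$value
  rotated <- iterative_mmd(walk, rotate_signal(walk, 45), cfg)$value
  expect_lt(same, rotated)
})
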