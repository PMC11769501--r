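test_that("standardization uses training statistics only", {
  set.seed(1)
  x <- matrix(rnorm(300, mean = 2, sd = 3), ncol = 3L)
  out <- standardize(x)
  expect_equal(colMeans(out$series), rep(0, 3L), tolerance = 1e-9)
  expect_equal(sqrt(colMeans(sweep(out$series, 2L, colMeans(out$series))^2)),
               rep(1, 3L), tolerance = 1e-9)

  # hand z-score with population sd: train channel (0, 2) -> mean 1, sd 1
  train <- cbind(c(0, 2), c(0, 2), c(0, 2))
  res <- standardize(train, apply_to = matrix(3, 1L, 3L))
  expect_equal(res$stats$mean, rep(1, 3L))
  expect_equal(res$stats$sd, rep(1, 3L))
  expect_equal(as.vector(res$series), rep(2, 3L))

  const <- cbind(rnorm(10), rep(5, 10), rnorm(10))
  expect_error(standardize(const), "zero-variance.*y")
})

test_that("window arithmetic matches the 2 s design at both device rates", {
  set.seed(2)
  x <- matrix(rnorm(3000), ncol = 3L)
  lab <- rep(0L, 1000L)
  expect_identical(dim(make_windows(x, lab, 64)$windows)[2L], 128L)
  expect_identical(dim(make_windows(x, lab, 100)$windows)[2L], 200L)
  # 1000 samples at 100 Hz, 2 s windows, 1 s hop -> 9 windows
  expect_identical(dim(make_windows(x, lab, 100, 2, 1)$windows)[1L], 9L)
})

test_that("windows are half-open and reconstruct the series at step = L", {
  x <- matrix(seq_len(120), ncol = 3L)  # 40 samples
  lab <- rep(c(0L, 1L), each = 20L)
  ws <- make_windows(x, lab, rate_hz = 5, window_s = 2, step_s = 2)  # L = 10
  expect_identical(dim(ws$windows), c(4L, 10L, 3L))
  rebuilt <- do.call(rbind, lapply(1:4, function(i) ws$windows[i, , ]))
  expect_equal(rebuilt, unname(x))
  expect_identical(ws$labels, c(0L, 0L, 1L, 1L))
})

test_that("window labels use majority vote with ties to not-walking", {
  x <- matrix(0, 10L, 3L)
  expect_identical(make_windows(x, c(rep(0L, 4L), rep(1L, 6L)), 5, 2, 2)$labels, 1L)
  expect_identical(make_windows(x, c(rep(0L, 5L), rep(1L, 5L)), 5, 2, 2)$labels, 0L)
  expect_warning(short <- make_windows(matrix(0, 3L, 3L), rep(0L, 3L), 5, 2, 2),
                 "shorter")
  expect_identical(dim(short$windows)[1L], 0L)
})

test_that("window resampling is exact on affine inputs and accurate on sinusoids", {
  ramp <- cbind(seq(0, 1, length.out = 128L), seq(2, 5, length.out = 128L),
                seq(-1, 1, length.out = 128L))
  expect_identical(resample_window(ramp, 128L), ramp)
  up <- resample_window(ramp, 200L)
  expect_equal(up[, 1L], seq(0, 1, length.out = 200L), tolerance = 1e-12)
  expect_equal(up[1L, ], ramp[1L, ], tolerance = 1e-15)
  expect_equal(up[200L, ], ramp[128L, ], tolerance = 1e-15)
  # round trip on affine input
  expect_equal(resample_window(up, 128L), ramp, tolerance = 1e-9)

  # 2 Hz unit sinusoid sampled at 64 Hz, upsampled to 200 samples over 2 s
  t64 <- (0:127) / 64
  t200 <- seq(0, t64[128L], length.out = 200L)
  sine <- matrix(sin(2 * pi * 2 * t64), ncol = 1L)
  up <- resample_window(cbind(sine, sine, sine), 200L)
  expect_lt(max(abs(up[, 1L] - sin(2 * pi * 2 * t200))), 0.01)
  expect_error(resample_window(ramp, 1L), "target_len")
})

test_that("inverse-frequency weights balance classes under weighted sampling", {
  lab <- c(rep(0L, 200L), rep(1L, 100L))
  w <- sample_weights(lab)
  expect_equal(w[lab == 1L][1L] / w[lab == 0L][1L], 2)
  expect_equal(sample_weights(rep(c(0L, 1L), 50L)), rep(1, 100L))
  set.seed(99)
  draws <- sample(lab, 1e5, replace = TRUE, prob = w)
  expect_equal(mean(draws == 1L), 0.5, tolerance = 0.01)
})

test_that("train/validation split is a deterministic 9:1 partition", {
  ws <- make_separable_windows(100L)
  sp <- split_train_val(ws, seed = 4L)
  expect_identical(length(sp$train$labels), 90L)
  expect_identical(length(sp$val$labels), 10L)
  sp2 <- split_train_val(ws, seed = 4L)
  expect_identical(sp$val$windows, sp2$val$windows)
  # partition property via window checksums
  key <- function(w) apply(w, 1L, function(m) sum(m * seq_along(m)))
  all_keys <- sort(c(key(sp$train$windows), key(sp$val$windows)))
  expect_equal(all_keys, sort(key(ws$windows)))
  expect_error(split_train_val(make_separable_windows(8L)), "at least 10")
})

test_that("no training statistic depends on held-out data", {
  set.seed(5)
  train <- matrix(rnorm(300), ncol = 3L)
  test <- matrix(rnorm(300, mean = 50), ncol = 3L)  # wildly different
  a <- standardize(train)
  b <- standardize(train, apply_to = test)
  expect_identical(a$stats, b$stats)
})

test_that("window sets round-trip through the binary writer with sidecar", {
  ws <- make_separable_windows(12L)
  path <- withr::local_tempfile(fileext = ".bin")
  write_window_set(ws, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_window_set(path)
  expect_equal(back$windows, ws$windows)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(as.integer(unlist(side$shape)), dim(ws$windows))
})
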