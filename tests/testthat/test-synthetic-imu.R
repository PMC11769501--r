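test_that("cohorts are deterministic and respect the sidebar design", {
  cohort <- make_cohort(16L, sidebar_ids = c(2L, 4L, 9L), seed = 7L)
  expect_length(cohort, 16L)
  holders <- vapply(cohort, function(p) p$holds_sidebar, TRUE)
  expect_identical(which(holders), c(2L, 4L, 9L))
  for (p in cohort) {
    expect_equal(sum(p$harmonic_weights), 1, tolerance = 1e-9)
    expect_gte(p$step_freq_base, 1.2)
    expect_lte(p$step_freq_base, 2.4)
    expect_gt(p$amp_scale, 0)
  }
  again <- make_cohort(16L, sidebar_ids = c(2L, 4L, 9L), seed = 7L)
  expect_identical(cohort, again)
  expect_error(make_cohort(0L), "positive")
  expect_error(make_cohort(4L, sidebar_ids = 9L), "subset")
})

test_that("a full-length session has the designed walking sample counts", {
  p <- make_cohort(1L, seed = 3L)[[1L]]
  sensors <- harvar_sensors()
  rec64 <- simulate_session(p, sensors["EL"], walk_min_per_speed = 2,
                            nonwalk_min = 1)$EL
  rec100 <- simulate_session(p, sensors["BR1"], walk_min_per_speed = 2,
                             nonwalk_min = 1)$BR1
  expect_identical(sum(rec64$labels == 1L), 38400L)
  expect_identical(sum(rec100$labels == 1L), 60000L)
  expect_identical(nrow(rec64$samples), length(rec64$labels))
  expect_false(anyNA(rec64$samples))
})

test_that("sessions are deterministic and identical sensors coincide", {
  p <- make_cohort(1L, seed = 5L)[[1L]]
  twin <- list(a = sensor_spec("X1", "right", 0, 64, 0.02, "B"),
               b = sensor_spec("X1", "right", 0, 64, 0.02, "B"))
  recs <- simulate_session(p, twin, walk_min_per_speed = 0.1, nonwalk_min = 0.5)
  expect_identical(recs[[1L]]$samples, recs[[2L]]$samples)
  again <- simulate_session(p, twin, walk_min_per_speed = 0.1, nonwalk_min = 0.5)
  expect_identical(recs[[1L]]$samples, again[[1L]]$samples)
  expect_error(simulate_session(p, list()), "non-empty")
})

test_that("rotation-only sensor pairs are isometric and time aligned", {
  p <- make_cohort(1L, seed = 9L)[[1L]]
  pair <- list(r0 = sensor_spec("R0", "right", 0, 100, 0, "A"),
               r45 = sensor_spec("R45", "right", 45, 100, 0, "A"),
               e0 = sensor_spec("E0", "right", 0, 64, 0, "A"))
  recs <- simulate_session(p, pair, walk_min_per_speed = 0.1, nonwalk_min = 0.5)
  n0 <- sqrt(rowSums(recs$r0$samples^2))
  n45 <- sqrt(rowSums(recs$r45$samples^2))
  expect_lt(max(abs(n0 - n45)), 1e-9)
  # label streams agree after resampling indices by the rate ratio
  idx <- floor((seq_along(recs$e0$labels) - 1L) * 100 / 64) + 1L
  idx <- pmin(idx, length(recs$r0$labels))
  expect_identical(recs$e0$labels, recs$r0$labels[idx])
})

test_that("rotate_signal behaves as a Z-axis rotation", {
  x <- matrix(rnorm(300), ncol = 3L)
  expect_equal(rotate_signal(x, 0), x, tolerance = 1e-12)
  expect_equal(rotate_signal(rotate_signal(x, 45), 45), rotate_signal(x, 90),
               tolerance = 1e-12)
  expect_equal(as.vector(rotate_signal(matrix(c(1, 0, 0), 1L), 90)),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(rotate_signal(x, 123)^2)), sqrt(rowSums(x^2)),
               tolerance = 1e-12)
})

test_that("label_ratio reproduces the 2:1 class design and rejects degenerate input", {
  p <- make_cohort(1L, seed = 2L)[[1L]]
  rec <- simulate_session(p, harvar_sensors()["EL"], walk_min_per_speed = 0.2,
                          nonwalk_min = 2)$EL
  expect_equal(label_ratio(rec), 2, tolerance = 0.05)
  expect_equal(label_ratio(rep(c(0L, 1L), 50L)), 1)
  expect_equal(label_ratio(c(rep(0L, 600L), rep(1L, 300L))), 2)
  expect_error(label_ratio(rep(1L, 10L)), "both classes")
})

test_that("sidebar holders produce markedly lower walking-signal variance", {
  cohort <- simulate_cohort(make_cohort(8L, sidebar_ids = c(2L, 5L), seed = 21L),
                            harvar_sensors()["ER"], walk_min_per_speed = 0.2,
                            nonwalk_min = 0.2)
  window_var <- function(rec) {
    ws <- make_windows(rec, window_s = 2, step_s = 2)
    walk <- ws$windows[ws$labels == 1L, , , drop = FALSE]
    mean(apply(walk, 1L, function(w) mean(apply(w, 2L, stats::var))))
  }
  v <- vapply(cohort$sessions, function(s) window_var(s$ER), 0)
  holders <- vapply(cohort$profiles, function(p) p$holds_sidebar, TRUE)
  expect_lt(mean(v[holders]), 0.4 * mean(v[!holders]))
})

test_that("sessions round-trip through the CSV writer and manifest", {
  p <- make_cohort(1L, seed = 13L)[[1L]]
  session <- simulate_session(p, harvar_sensors()[c("EL", "BR1")],
                              walk_min_per_speed = 0.05, nonwalk_min = 0.1)
  dir <- withr::local_tempdir()
  write_session_csv(session, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_session_csv(dir)
  expect_equal(back$EL$samples, session$EL$samples, tolerance = 1e-12)
  expect_identical(back$EL$labels, session$EL$labels)
  expect_identical(back$BR1$sensor$rate_hz, 100)
})
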