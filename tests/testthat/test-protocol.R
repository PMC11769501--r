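test_that("f1_score matches hand-computed values and validates input", {
  expect_identical(f1_score(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L)), 1)
  expect_identical(f1_score(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L)), 0)
  # TP = 40, FP = 10, FN = 20 for the positive class
  true <- c(rep(1L, 60L), rep(0L, 40L))
  pred <- c(rep(1L, 40L), rep(0L, 20L), rep(1L, 10L), rep(0L, 30L))
  expect_equal(f1_score(true, pred, scheme = "positive_class"),
               2 * 40 / (2 * 40 + 10 + 20), tolerance = 1e-4)
  expect_error(f1_score(c(0L, 1L), c(0L, 2L)), "unseen")
  expect_error(f1_score(integer(), integer()), "non-empty")
  # macro averaging with an excluded null class
  expect_equal(f1_score(c(0L, 1L, 2L, 1L, 2L), c(0L, 1L, 2L, 1L, 2L),
                        exclude_classes = 0L), 1)
})

test_that("the paired t-test reproduces the reference t distribution and stars", {
  set.seed(1)
  base <- 0.8 + rnorm(16L, sd = 0.005)
  vari <- base - 0.2 + rnorm(16L, sd = 0.001)
  res <- paired_ttest(base, vari)
  expect_lt(res$p_value, 0.001)
  expect_identical(res$stars, "***")
  # closed-form oracle for the paired statistic
  d <- base - vari
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * stats::pt(-abs(tstat), df = length(d) - 1L)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, p_ref, tolerance = 1e-12)

  same <- paired_ttest(base, base)
  expect_true(same$degenerate)
  expect_identical(same$stars, "ns")
  expect_error(paired_ttest(1:2, 1:2), "at least 3")
})

test_that("star coding follows the 0.05 / 0.01 / 0.001 thresholds", {
  stars <- vapply(c(0.2, 0.049, 0.009, 0.0009), harshift:::.stars_for_p, "")
  expect_identical(stars, c("ns", "*", "**", "***"))
})

test_that("MMD-F1 correlation recovers exact linear relations and flags degeneracy", {
  mmd <- c(0.5, 1, 1.5, 2, 3)
  df <- data.frame(mmd = mmd, f1 = 1 - 0.1 * mmd)
  res <- mmd_f1_correlation(df)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  flat <- mmd_f1_correlation(data.frame(mmd = mmd, f1 = rep(0.5, 5L)))
  expect_true(flat$undefined)
  expect_error(mmd_f1_correlation(data.frame(mmd = 1, f1 = 1)), "at least 3")
})

test_that("experiment specs enforce the shared-test-sensor design", {
  expect_error(experiment_spec("e", "position", "ER", "EL", "baseline"),
               "same sensor")
  ex <- harvar_experiments()
  expect_length(ex, 8L)
  for (e in ex) {
    expect_identical(e$baseline$test_sensor, e$variability$test_sensor)
    expect_identical(e$baseline$train_sensor, e$baseline$test_sensor)
  }
  types <- vapply(ex, function(e) e$variability$variability_type, "")
  expect_identical(sum(types == "position"), 4L)
  expect_identical(sum(types == "device"), 2L)
  expect_identical(sum(types == "orientation"), 2L)
})

cohort <- tiny_cohort(n_subjects = 4L, sidebar_ids = integer(), seed = 19L)

test_that("a baseline LOSO run on separable synthetic data performs well", {
  # six subjects so the training population covers enough gait variation
  cohort6 <- tiny_cohort(n_subjects = 6L, sidebar_ids = integer(), seed = 19L)
  spec <- experiment_spec("exp1", "position", "EL", "EL", "baseline")
  res <- run_experiment(spec, cohort6, "tinyhar", test_train_config(),
                        mmd_config(iterations = 60L), step_s = 1, seed = 3L)
  expect_identical(nrow(res$per_fold), 6L)  # fold count = number of subjects
  expect_gte(res$mean_f1, 0.9)
  expect_equal(res$mean_f1, mean(res$per_fold$f1), tolerance = 1e-12)
  expect_true(all(res$per_fold$mmd >= 0))
})

test_that("baseline and variability settings share the identical raw test windows", {
  base <- experiment_spec("exp1", "position", "EL", "EL", "baseline")
  vari <- experiment_spec("exp1", "position", "ER", "EL", "variability")
  cfg <- test_train_config(max_epochs = 1L)
  r1 <- run_experiment(base, cohort, "tinyhar", cfg,
                       mmd_config(iterations = 5L), seed = 1L)
  r2 <- run_experiment(vari, cohort, "tinyhar", cfg,
                       mmd_config(iterations = 5L), seed = 1L)
  for (i in seq_along(r1$test_checksums)) {
    expect_identical(r1$test_checksums[[i]], r2$test_checksums[[i]])
  }
})

test_that("device-variability folds resample every test window", {
  # train at 100 Hz (L = 200), test at 64 Hz (L = 128): predictions exist for
  # every test window, which requires the upsampling path
  spec <- experiment_spec("exp5", "device", "BL", "EL", "variability")
  res <- run_experiment(spec, cohort, "tinyhar", test_train_config(max_epochs = 2L),
                        mmd_config(iterations = 5L), seed = 2L)
  expect_identical(nrow(res$per_fold), 4L)
  expect_true(all(is.finite(res$per_fold$f1)))
})

test_that("held-out subjects never contribute to normalisation statistics", {
  held <- "1"
  train_subjects <- setdiff(names(cohort$sessions), held)
  recs <- lapply(train_subjects, function(s) cohort$sessions[[s]][["EL"]])
  direct <- standardize(recs)$stats
  # corrupt the held-out subject's recording; the statistics must not move
  mutated <- cohort
  mutated$sessions[[held]]$EL$samples <- mutated$sessions[[held]]$EL$samples + 1e6
  recs2 <- lapply(train_subjects, function(s) mutated$sessions[[s]][["EL"]])
  expect_identical(standardize(recs2)$stats, direct)
})

test_that("two runs with the same master seed yield identical result tables", {
  spec <- experiment_spec("exp7", "orientation", "BR1", "BR2", "variability")
  cfg <- test_train_config(max_epochs = 2L)
  r1 <- run_experiment(spec, cohort, "tinyhar", cfg, mmd_config(iterations = 20L),
                       seed = 7L)
  r2 <- run_experiment(spec, cohort, "tinyhar", cfg, mmd_config(iterations = 20L),
                       seed = 7L)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("missing sensors are reported as a configuration error", {
  broken <- cohort
  broken$sessions[["2"]]$EL <- NULL
  spec <- experiment_spec("exp1", "position", "ER", "EL", "variability")
  expect_error(run_experiment(spec, broken), "subject 2 is missing.*EL")
})
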