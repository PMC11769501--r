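# Baseline-vs-variability leave-one-subject-out (LOSO) experiments and the
# statistics connecting distribution shift (MMD) to model performance (F1).

#' Describe one evaluation setting
#'
#' A baseline setting trains and tests on the same sensor; a variability
#' setting trains on a different sensor but keeps the identical test sensor,
#' so the two settings of an experiment isolate one variability factor.
#'
#' @param experiment_id Identifier (e.g. `"exp1"`).
#' @param variability_type One of `"position"`, `"device"`, `"orientation"`,
#'   `"compound"`.
#' @param train_sensor,test_sensor Sensor codes.
#' @param setting `"baseline"` or `"variability"`.
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(experiment_id, variability_type =
                              c("position", "device", "orientation", "compound"),
                            train_sensor, test_sensor,
                            setting = c("baseline", "variability")) {
  variability_type <- match.arg(variability_type)
  setting <- match.arg(setting)
  if (setting == "baseline" && !identical(train_sensor, test_sensor)) {
    stop_invalid("baseline settings must train and test on the same sensor (got %s vs %s)",
                 train_sensor, test_sensor)
  }
  structure(list(experiment_id = experiment_id,
                 variability_type = variability_type,
                 train_sensor = train_sensor, test_sensor = test_sensor,
                 setting = setting),
            class = "experiment_spec")
}

#' The eight sensor-pair experiments of the study design
#'
#' Four position pairs, two device pairs and two orientation pairs; each
#' experiment is a (variability, baseline) couple sharing its test sensor.
#'
#' @return List of experiments, each with `variability` and `baseline`
#'   [experiment_spec()]s.
#' @export
harvar_experiments <- function() {
  def <- list(
    list("exp1", "position", "ER", "EL"),
    list("exp2", "position", "EL", "ER"),
    list("exp3", "position", "BR1", "BL"),
    list("exp4", "position", "BL", "BR1"),
    list("exp5", "device", "BL", "EL"),
    list("exp6", "device", "EL", "BL"),
    list("exp7", "orientation", "BR1", "BR2"),
    list("exp8", "orientation", "BR2", "BR1")
  )
  lapply(def, function(d) {
    list(variability = experiment_spec(d[[1]], d[[2]], d[[3]], d[[4]], "variability"),
         baseline = experiment_spec(d[[1]], d[[2]], d[[4]], d[[4]], "baseline"))
  })
}

#' F1 score
#'
#' @param true_labels,predicted_labels Equal-length label vectors. Predicted
#'   codes must all occur among the true codes.
#' @param scheme `"macro"` (mean of per-class F1, the default) or
#'   `"positive_class"` (F1 of `positive` only).
#' @param positive Positive class code for `scheme = "positive_class"`.
#' @param exclude_classes Class codes dropped from macro averaging (e.g. a
#'   null class).
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(true_labels, predicted_labels,
                     scheme = c("macro", "positive_class"), positive = 1L,
                     exclude_classes = NULL) {
  scheme <- match.arg(scheme)
  if (length(true_labels) == 0L || length(true_labels) != length(predicted_labels)) {
    stop_invalid("label vectors must be non-empty and of equal length")
  }
  classes <- sort(unique(true_labels))
  if (!all(predicted_labels %in% classes)) {
    stop_invalid("predicted labels contain codes unseen in the true labels: %s",
                 paste(setdiff(unique(predicted_labels), classes), collapse = ","))
  }
  per_class_f1 <- function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  if (scheme == "positive_class") {
    return(per_class_f1(positive))
  }
  use <- setdiff(classes, exclude_classes)
  if (length(use) == 0L) stop_invalid("no classes left after exclusion")
  mean(vapply(use, per_class_f1, 0))
}

.stars_for_p <- function(p) {
  if (is.na(p)) "ns"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Paired t-test between per-subject baseline and variability scores
#'
#' Two-tailed paired t-test on fold-wise differences, with the conventional
#' star coding (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param baseline_f1s,variability_f1s Equal-length (>= 3) vectors paired by
#'   subject.
#' @return A `stat_result`: `p_value`, `stars`, `statistic`, `df`,
#'   `degenerate` (TRUE when all differences are zero-variance, in which
#'   case the statistic is undefined and stars are `"ns"`).
#' @export
paired_ttest <- function(baseline_f1s, variability_f1s) {
  if (length(baseline_f1s) != length(variability_f1s) || length(baseline_f1s) < 3L) {
    stop_invalid("need equal-length paired vectors with at least 3 folds")
  }
  d <- baseline_f1s - variability_f1s
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    return(structure(list(p_value = NA_real_, stars = "ns",
                          statistic = NA_real_, df = length(d) - 1L,
                          degenerate = TRUE),
                     class = "stat_result"))
  }
  tt <- stats::t.test(baseline_f1s, variability_f1s, paired = TRUE)
  structure(list(p_value = tt$p.value, stars = .stars_for_p(tt$p.value),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 degenerate = FALSE),
            class = "stat_result")
}

#' Pearson correlation between per-fold MMD and F1
#'
#' @param results An `experiment_result`, a list of them, or a data.frame
#'   with columns `mmd` and `f1`.
#' @return A `stat_result` with `pearson_r`, `p_value`, `stars` and
#'   `undefined` (TRUE when either variable has zero variance).
#' @export
mmd_f1_correlation <- function(results) {
  df <- .fold_table(results)
  df <- df[is.finite(df$mmd) & is.finite(df$f1), , drop = FALSE]
  if (nrow(df) < 3L) stop_invalid("need at least 3 folds with finite MMD and F1")
  if (stats::sd(df$mmd) == 0 || stats::sd(df$f1) == 0) {
    return(structure(list(pearson_r = NA_real_, p_value = NA_real_,
                          stars = "ns", undefined = TRUE),
                     class = "stat_result"))
  }
  ct <- stats::cor.test(df$mmd, df$f1, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 stars = .stars_for_p(ct$p.value), undefined = FALSE),
            class = "stat_result")
}

.fold_table <- function(results) {
  if (is.data.frame(results)) return(results)
  if (inherits(results, "experiment_result")) return(results$per_fold)
  do.call(rbind, lapply(results, function(r) {
    if (inherits(r, "experiment_result")) r$per_fold else as.data.frame(r)
  }))
}

#' Run one LOSO evaluation setting
#'
#' For each held-out subject: standardize the remaining subjects' training
#' sensor recordings (pooled statistics), train the model on their sliding
#' windows with a class-weighted sampler, test on the held-out subject's
#' test-sensor windows (resampled to the training window length when the
#' rates differ), and record the macro F1 together with the per-fold
#' walking-class MMD between the standardized training and testing series.
#'
#' @param spec An [experiment_spec()].
#' @param cohort A `har_cohort` from [simulate_cohort()].
#' @param arch Architecture name (see [model_config()]).
#' @param train_cfg A [train_config()].
#' @param mmd_cfg An [mmd_config()] for the per-fold shift estimate.
#' @param window_s,step_s Sliding-window length and hop in seconds.
#' @param mmd_classes Class codes entering the MMD (default: walking only).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return An `experiment_result`: `spec`, `arch`, `per_fold` (data.frame
#'   with subject, f1, mmd), `mean_f1`, `sd_f1`, `mean_mmd`, and a raw
#'   test-window checksum per fold for isolation checks.
#' @export
run_experiment <- function(spec, cohort, arch = "deepconvlstm",
                           train_cfg = fast_train_config(),
                           mmd_cfg = mmd_config(iterations = 2000L),
                           window_s = 2, step_s = 1, mmd_classes = 1L,
                           seed = 1L) {
  stopifnot(inherits(spec, "experiment_spec"), inherits(cohort, "har_cohort"))
  subjects <- names(cohort$sessions)
  for (s in subjects) {
    have <- names(cohort$sessions[[s]])
    missing <- setdiff(c(spec$train_sensor, spec$test_sensor), have)
    if (length(missing)) {
      stop_invalid("subject %s is missing sensor(s): %s", s,
                   paste(missing, collapse = ", "))
    }
  }
  folds <- lapply(subjects, function(held) {
    .run_fold(held, spec, cohort, arch, train_cfg, mmd_cfg, window_s, step_s,
              mmd_classes, seed)
  })
  per_fold <- do.call(rbind, lapply(folds, function(f) f$row))
  structure(list(spec = spec, arch = arch, per_fold = per_fold,
                 mean_f1 = mean(per_fold$f1), sd_f1 = stats::sd(per_fold$f1),
                 mean_mmd = mean(per_fold$mmd),
                 test_checksums = lapply(folds, function(f) f$checksum)),
            class = "experiment_result")
}

.run_fold <- function(held, spec, cohort, arch, train_cfg, mmd_cfg, window_s,
                      step_s, mmd_classes, seed) {
  train_subjects <- setdiff(names(cohort$sessions), held)
  train_recs <- lapply(train_subjects, function(s) cohort$sessions[[s]][[spec$train_sensor]])
  test_rec <- cohort$sessions[[held]][[spec$test_sensor]]
  raw_checksum <- num_checksum(test_rec$samples)

  std <- standardize(train_recs)
  train_std <- std$series
  test_std <- apply_standardization(test_rec, std$stats)

  train_ws <- bind_window_sets(lapply(seq_along(train_std), function(i) {
    rec <- train_recs[[i]]
    make_windows(train_std[[i]], rec$labels, rec$rate_hz, window_s, step_s,
                 subject_id = rec$subject_id, sensor_code = rec$sensor$code)
  }))
  train_ws$norm_stats <- std$stats
  test_ws <- make_windows(test_std, window_s = window_s, step_s = step_s)

  # common random numbers: the training seed depends only on (arch, fold),
  # never on the setting, so the baseline and variability runs of one
  # experiment share initialisation and sampling streams and training luck
  # cancels from the paired comparison
  fold_seed <- derive_seed(seed, arch, held)
  cfg <- train_cfg
  cfg$seed <- fold_seed
  input_len <- as.integer(round(window_s * train_recs[[1L]]$rate_hz))
  model <- build_model(model_config(arch, input_len,
                                    n_classes = length(unique(train_ws$labels)),
                                    seed = derive_seed(fold_seed, "init")))
  fit <- train_model(model, train_ws, cfg)
  pred <- predict_labels(fit$model, test_ws, classes = fit$classes)
  f1 <- f1_score(test_ws$labels, pred, scheme = "macro")

  mcfg <- mmd_cfg
  mcfg$seed <- derive_seed(fold_seed, "mmd")
  train_series <- do.call(rbind, lapply(train_std, function(r) r$samples))
  train_labels <- unlist(lapply(train_recs, function(r) r$labels))
  shift <- per_class_mmd(train_series, train_labels, test_std$samples,
                         test_rec$labels, classes_to_use = mmd_classes,
                         config = mcfg)
  list(row = data.frame(subject = as.integer(held), f1 = f1, mmd = shift$mean),
       checksum = raw_checksum)
}

#' Run a set of baseline/variability experiments with shared work
#'
#' Evaluates each requested experiment couple; identical
#' (train sensor, test sensor) settings are computed once and reused (several
#' experiments share a baseline).
#'
#' @param cohort A `har_cohort`.
#' @param experiments List of experiment couples, as from
#'   [harvar_experiments()] (possibly subset).
#' @param arch,train_cfg,mmd_cfg,window_s,step_s,seed As [run_experiment()].
#' @return List with `results` (per experiment couple: `baseline`,
#'   `variability` experiment_results plus the paired t-test) and `summary`
#'   (data.frame of mean F1 / MMD per experiment and setting).
#' @export
run_study <- function(cohort, experiments = harvar_experiments(),
                      arch = "deepconvlstm", train_cfg = fast_train_config(),
                      mmd_cfg = mmd_config(iterations = 2000L), window_s = 2,
                      step_s = 1, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  eval_spec <- function(spec) {
    key <- paste(spec$train_sensor, spec$test_sensor, sep = ">")
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, run_experiment(spec, cohort, arch, train_cfg, mmd_cfg,
                                 window_s, step_s, seed = seed),
             envir = cache)
    }
    res <- get(key, envir = cache)
    res$spec <- spec  # reuse measurements, keep the requesting spec
    res
  }
  results <- lapply(experiments, function(ex) {
    base <- eval_spec(ex$baseline)
    vari <- eval_spec(ex$variability)
    list(experiment_id = ex$baseline$experiment_id,
         variability_type = ex$baseline$variability_type,
         baseline = base, variability = vari,
         ttest = paired_ttest(base$per_fold$f1, vari$per_fold$f1))
  })
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      experiment_id = r$experiment_id,
      variability_type = r$variability_type,
      train_sensor = r$variability$spec$train_sensor,
      test_sensor = r$variability$spec$test_sensor,
      baseline_f1 = r$baseline$mean_f1, variability_f1 = r$variability$mean_f1,
      f1_drop = r$baseline$mean_f1 - r$variability$mean_f1,
      baseline_mmd = r$baseline$mean_mmd,
      variability_mmd = r$variability$mean_mmd,
      p_value = r$ttest$p_value, stars = r$ttest$stars
    )
  }))
  list(results = results, summary = summary)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s [%s] train %s -> test %s (%s): F1 %.3f +- %.3f, MMD %.3f\n",
              x$spec$experiment_id, x$arch, x$spec$train_sensor,
              x$spec$test_sensor, x$spec$setting, x$mean_f1, x$sd_f1,
              x$mean_mmd))
  invisible(x)
}

#' @export
print.stat_result <- function(x, ...) {
  if (!is.null(x$pearson_r)) {
    cat(sprintf("<stat_result> r = %.3f, p = %.3g (%s)\n",
                x$pearson_r, x$p_value, x$stars))
  } else {
    cat(sprintf("<stat_result> t = %.3f (df %g), p = %.3g (%s)\n",
                x$statistic, x$df, x$p_value, x$stars))
  }
  invisible(x)
}
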