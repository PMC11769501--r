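# Compounding-variability case study in the style of the REALDISP
# ideal/self sensor-placement dataset: a reader for the space-separated
# per-subject .log files, a synthetic stand-in generator, and the four
# train/test placement scenarios evaluated with LOSO.

#' Column map for REALDISP-style .log files
#'
#' Each line of a .log file holds two time columns, thirteen channels
#' (3 acceleration, 3 gyroscope, 3 magnetometer, 4 quaternion) for each of
#' nine inertial units, and one integer activity label. The default unit
#' order is assumed to be RLA, RUA, BACK, LUA, LLA, RC, RT, LC, LT; pass your
#' own order if the copy of the dataset documents a different one.
#'
#' @param units Character vector naming the nine sensor blocks in file order.
#' @return Named list mapping each unit to its three accelerometer column
#'   indices, plus `label` (the label column index) and `n_cols`.
#' @export
realdisp_column_map <- function(units = c("RLA", "RUA", "BACK", "LUA", "LLA",
                                          "RC", "RT", "LC", "LT")) {
  per_unit <- 13L
  m <- lapply(seq_along(units), function(i) 2L + (i - 1L) * per_unit + 1:3)
  names(m) <- units
  m$label <- 2L + length(units) * per_unit + 1L
  m$n_cols <- m$label
  m
}

#' Read one REALDISP-style .log file
#'
#' @param path Path to a space-separated .log file.
#' @param unit Sensor unit whose accelerometer channels to extract (e.g.
#'   `"RLA"` or `"LLA"`).
#' @param column_map A [realdisp_column_map()].
#' @param rate_hz Sampling rate of the dataset (50 Hz).
#' @return List with `samples` (N x 3), `labels` (N), `rate_hz`.
#' @export
read_realdisp_log <- function(path, unit = "RLA",
                              column_map = realdisp_column_map(),
                              rate_hz = 50) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  if (!unit %in% names(column_map)) {
    stop_invalid("unknown unit '%s'; column map has: %s", unit,
                 paste(setdiff(names(column_map), c("label", "n_cols")),
                       collapse = ", "))
  }
  df <- utils::read.table(path, header = FALSE)
  if (ncol(df) < column_map$n_cols) {
    stop_invalid("%s has %d columns; expected at least %d (2 time + 9 x 13 channels + label)",
                 path, ncol(df), column_map$n_cols)
  }
  list(samples = unname(as.matrix(df[, column_map[[unit]]])),
       labels = as.integer(df[[column_map$label]]),
       rate_hz = rate_hz)
}

#' Read a directory of REALDISP-style per-subject sessions
#'
#' Expects files `subject<N>_ideal.log` and `subject<N>_self.log`.
#'
#' @param dir Dataset directory.
#' @param unit Sensor unit (see [read_realdisp_log()]).
#' @param column_map A [realdisp_column_map()].
#' @return A `placement_data` list: `subjects` (per id: `ideal`, `self`
#'   series), `rate_hz`, `unit`.
#' @export
read_realdisp_dir <- function(dir, unit = "RLA",
                              column_map = realdisp_column_map()) {
  if (!dir.exists(dir)) {
    stop_invalid(paste0(
      "dataset directory not found: %s\nExpected layout: one directory with ",
      "files subject<N>_ideal.log and subject<N>_self.log (space-separated, ",
      "2 time columns + 9 sensor blocks of 13 channels + final integer ",
      "activity label). The dataset must be downloaded manually."), dir)
  }
  ideal <- sort(list.files(dir, pattern = "^subject[0-9]+_ideal\\.log$"))
  if (length(ideal) == 0L) {
    stop_invalid("no subject<N>_ideal.log files found in %s", dir)
  }
  ids <- sub("^subject([0-9]+)_ideal\\.log$", "\\1", ideal)
  subjects <- lapply(ids, function(id) {
    self_file <- file.path(dir, sprintf("subject%s_self.log", id))
    if (!file.exists(self_file)) {
      stop_invalid("subject %s has an ideal session but no self session (%s)",
                   id, self_file)
    }
    list(ideal = read_realdisp_log(file.path(dir, sprintf("subject%s_ideal.log", id)),
                                   unit, column_map),
         self = read_realdisp_log(self_file, unit, column_map))
  })
  names(subjects) <- ids
  structure(list(subjects = subjects, rate_hz = 50, unit = unit),
            class = "placement_data")
}

#' Simulate ideal/self placement sessions (synthetic stand-in)
#'
#' Generates per-subject sessions in which each activity class has a
#' distinct harmonic signature, separated by null-labelled rest gaps. The
#' "self" session replays the same latent motion through a per-subject
#' random placement perturbation: a rotation of up to 180 degrees about Z,
#' an occasional axis flip (sensor worn upside down), and a small gain
#' change from shifted placement along the arm. This emulates compounding
#' position and orientation variability; it is not the real REALDISP data.
#'
#' @param n_subjects Number of subjects.
#' @param n_classes Number of activity classes (labels 1..n_classes; 0 is
#'   the null class between blocks).
#' @param seconds_per_class Activity-block length in seconds.
#' @param gap_s Null gap between blocks in seconds.
#' @param rate_hz Sampling rate (50 Hz, as the dataset it emulates).
#' @param noise_sd White-noise standard deviation in g.
#' @param seed Integer seed.
#' @return A `placement_data` list (see [read_realdisp_dir()]).
#' @export
simulate_placement_data <- function(n_subjects = 4L, n_classes = 3L,
                                    seconds_per_class = 30, gap_s = 6,
                                    rate_hz = 50, noise_sd = 0.03, seed = 1L) {
  # class templates shared across subjects
  templates <- with_seed(derive_seed(seed, "templates"), {
    lapply(seq_len(n_classes), function(k) {
      list(freq = stats::runif(1L, 0.6, 2.8),
           amp = stats::runif(3L, 0.15, 0.55),
           harm = stats::runif(2L, 0.2, 0.8),
           phase = stats::runif(3L, 0, 2 * pi))
    })
  })
  block_s <- seconds_per_class + gap_s
  total_s <- n_classes * block_s
  n <- round(total_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz

  subjects <- lapply(seq_len(n_subjects), function(s) {
    sseed <- derive_seed(seed, "subject", s)
    pars <- with_seed(sseed, {
      list(amp_jit = stats::rlnorm(1L, 0, 0.15),
           freq_jit = stats::runif(1L, 0.92, 1.08),
           phase_jit = stats::runif(3L, 0, 2 * pi),
           self_rot = stats::runif(1L, -180, 180),
           self_flip = stats::runif(1L) < 0.3,
           self_gain = stats::rlnorm(1L, 0, 0.1))
    })
    x <- matrix(0, n, 3L)
    x[, 3L] <- 1
    labels <- integer(n)
    for (k in seq_len(n_classes)) {
      t0 <- (k - 1) * block_s
      sel <- t >= t0 & t < t0 + seconds_per_class
      tau <- t[sel] - t0
      tpl <- templates[[k]]
      f <- tpl$freq * pars$freq_jit
      for (j in 1:3) {
        x[sel, j] <- x[sel, j] + pars$amp_jit * tpl$amp[j] *
          (sin(2 * pi * f * tau + tpl$phase[j] + pars$phase_jit[j]) +
             tpl$harm[1L] * sin(2 * pi * 2 * f * tau + tpl$phase[j]) +
             tpl$harm[2L] * sin(2 * pi * 3 * f * tau + 2 * tpl$phase[j]))
      }
      labels[sel] <- k
    }
    noise <- function(tag) {
      with_seed(derive_seed(sseed, tag), matrix(stats::rnorm(n * 3L, sd = noise_sd), n, 3L))
    }
    ideal <- x + noise("ideal")
    xs <- rotate_signal(x, pars$self_rot)
    if (pars$self_flip) xs[, 1L] <- -xs[, 1L]
    xs <- xs * pars$self_gain
    self <- xs + noise("self")
    list(ideal = list(samples = ideal, labels = labels, rate_hz = rate_hz),
         self = list(samples = self, labels = labels, rate_hz = rate_hz))
  })
  names(subjects) <- as.character(seq_len(n_subjects))
  structure(list(subjects = subjects, rate_hz = rate_hz, unit = "synthetic"),
            class = "placement_data")
}

#' The four placement scenarios
#' @return Data frame of scenario id, train placement, test placement.
#' @export
placement_scenarios <- function() {
  data.frame(
    scenario = c("ideal_ideal", "self_ideal", "self_self", "ideal_self"),
    train = c("ideal", "self", "self", "ideal"),
    test = c("ideal", "ideal", "self", "self")
  )
}

#' Evaluate the four placement scenarios with LOSO
#'
#' For each scenario (Ideal/Ideal, Self/Ideal, Self/Self, Ideal/Self), each
#' LOSO fold trains on the other subjects' training-placement sessions and
#' tests on the held-out subject's testing-placement session. Null-labelled
#' windows are excluded from classification and the null class from the MMD;
#' the per-fold MMD is the per-activity iterative MMD averaged over the
#' activity classes.
#'
#' @param data A `placement_data` (from [read_realdisp_dir()] or
#'   [simulate_placement_data()]).
#' @param arch Architecture name.
#' @param train_cfg A [train_config()].
#' @param mmd_cfg An [mmd_config()].
#' @param window_s,step_s Sliding-window length and hop in seconds.
#' @param seed Master seed.
#' @return List with `results` (per scenario: an `experiment_result`) and
#'   `summary` (data.frame of scenario, mean F1, mean MMD).
#' @export
run_realdisp_scenarios <- function(data, arch = "deepconvlstm",
                                   train_cfg = fast_train_config(),
                                   mmd_cfg = mmd_config(iterations = 2000L),
                                   window_s = 2, step_s = 1, seed = 1L) {
  stopifnot(inherits(data, "placement_data"))
  scen <- placement_scenarios()
  subjects <- names(data$subjects)
  classes <- sort(setdiff(unique(data$subjects[[1L]]$ideal$labels), 0L))

  results <- lapply(seq_len(nrow(scen)), function(si) {
    sc <- scen[si, ]
    folds <- lapply(subjects, function(held) {
      train_series <- lapply(setdiff(subjects, held),
                             function(s) data$subjects[[s]][[sc$train]]$samples)
      train_labels <- lapply(setdiff(subjects, held),
                             function(s) data$subjects[[s]][[sc$train]]$labels)
      test <- data$subjects[[held]][[sc$test]]

      std <- standardize(train_series)
      test_std <- apply_standardization(test$samples, std$stats)

      ws_list <- lapply(seq_along(std$series), function(i) {
        make_windows(std$series[[i]], train_labels[[i]], data$rate_hz,
                     window_s, step_s)
      })
      train_ws <- bind_window_sets(ws_list)
      keep <- train_ws$labels != 0L
      train_ws <- .subset_windows(train_ws, which(keep))
      test_ws <- make_windows(test_std, test$labels, data$rate_hz, window_s,
                              step_s)
      test_keep <- which(test_ws$labels != 0L)
      test_ws <- .subset_windows(test_ws, test_keep)

      fold_seed <- derive_seed(seed, sc$scenario, arch, held)
      cfg <- train_cfg
      cfg$seed <- fold_seed
      input_len <- as.integer(round(window_s * data$rate_hz))
      model <- build_model(model_config(arch, input_len,
                                        n_classes = length(classes),
                                        seed = derive_seed(fold_seed, "init")))
      fit <- train_model(model, train_ws, cfg)
      pred <- predict_labels(fit$model, test_ws, classes = fit$classes)
      f1 <- f1_score(test_ws$labels, pred, scheme = "macro")

      mcfg <- mmd_cfg
      mcfg$seed <- derive_seed(fold_seed, "mmd")
      shift <- per_class_mmd(do.call(rbind, std$series), unlist(train_labels),
                             test_std, test$labels, classes_to_use = classes,
                             config = mcfg)
      data.frame(subject = as.integer(held), f1 = f1, mmd = shift$mean)
    })
    per_fold <- do.call(rbind, folds)
    spec <- experiment_spec(sc$scenario, "compound",
                            paste0(data$unit, "-", sc$train),
                            paste0(data$unit, "-", sc$test),
                            if (sc$train == sc$test) "baseline" else "variability")
    structure(list(spec = spec, arch = arch, per_fold = per_fold,
                   mean_f1 = mean(per_fold$f1), sd_f1 = stats::sd(per_fold$f1),
                   mean_mmd = mean(per_fold$mmd)),
              class = "experiment_result")
  })
  names(results) <- scen$scenario
  summary <- cbind(scen, data.frame(
    mean_f1 = vapply(results, function(r) r$mean_f1, 0),
    sd_f1 = vapply(results, function(r) r$sd_f1, 0),
    mean_mmd = vapply(results, function(r) r$mean_mmd, 0)
  ))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
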