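# Training loop: Adam on cross-entropy with a class-weighted sampler, an
# internal shuffled 9:1 train/validation split, learning-rate annealing
# (factor 0.1) on validation-loss plateaus, early stopping, and best-epoch
# weight restoration.

#' Training configuration
#'
#' Defaults follow the study regime: batch 256, at most 150 epochs, early
#' stopping after 15 epochs without validation-loss improvement, initial
#' learning rate 0.001 annealed by 0.1 after 7 stale epochs, Adam on
#' cross-entropy.
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (may be `Inf`).
#' @param lr Initial learning rate.
#' @param anneal_patience Stale epochs before the learning rate is reduced.
#' @param anneal_factor Multiplicative learning-rate reduction.
#' @param val_ratio Fraction of windows held out for validation.
#' @param monitor Improvement monitor, `"loss"` (default) or `"f1"`.
#' @param max_restarts Number of times a run whose best validation macro F1
#'   stays below `restart_f1` is restarted from a fresh (derived-seed)
#'   initialisation. Occasional initialisations collapse to the majority
#'   class; deterministic restarts remove that failure mode without
#'   touching healthy runs.
#' @param restart_f1 Validation macro-F1 threshold below which a finished
#'   run counts as a collapsed initialisation.
#' @param seed Integer seed controlling the split, the sampler and weight
#'   initialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256L, max_epochs = 150L,
                         early_stop_patience = 15, lr = 0.001,
                         anneal_patience = 7L, anneal_factor = 0.1,
                         val_ratio = 0.1, monitor = c("loss", "f1"),
                         max_restarts = 2L, restart_f1 = 0.6,
                         seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(batch_size >= 1, max_epochs >= 1, lr > 0, anneal_factor > 0,
            anneal_patience >= 1, early_stop_patience >= 1)
  if (anneal_patience >= early_stop_patience) {
    stop_invalid("anneal_patience (%g) must be smaller than early_stop_patience (%g)",
                 anneal_patience, early_stop_patience)
  }
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience, lr = lr,
                 anneal_patience = anneal_patience,
                 anneal_factor = anneal_factor, val_ratio = val_ratio,
                 monitor = monitor, max_restarts = as.integer(max_restarts),
                 restart_f1 = restart_f1, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduced training profile for quick runs
#'
#' Same regime with at most 30 epochs and early-stopping patience 5
#' (annealing patience 3).
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
fast_train_config <- function(...) {
  args <- list(max_epochs = 30L, early_stop_patience = 5, anneal_patience = 3L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

#' Train a model on a window set
#'
#' Windows are split 9:1 into training and validation (shuffled,
#' deterministic given the seed). Each epoch draws training windows with
#' replacement under inverse-class-frequency weights, optimises the mean
#' cross-entropy with Adam, and evaluates validation loss and macro F1.
#' The learning rate is multiplied by `anneal_factor` after `anneal_patience`
#' epochs without improvement; training stops at `max_epochs` or after
#' `early_stop_patience` stale epochs; the best-validation weights are
#' restored before returning.
#'
#' @param model A `har_model` (freshly built; trained in place and returned).
#' @param train_windows A standardized `window_set` containing >= 2 classes.
#' @param config A [train_config()].
#' @return List with `model`, `history` (data.frame: epoch, train_loss,
#'   val_loss, val_f1, lr), `best_epoch`.
#' @export
train_model <- function(model, train_windows, config = train_config()) {
  labels <- train_windows$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop_invalid("training windows contain a single class (%s)",
                 paste(classes, collapse = ","))
  }
  split <- split_train_val(train_windows, ratio = config$val_ratio,
                           seed = derive_seed(config$seed, "split"))
  tr <- split$train
  va <- split$val
  ytr <- match(tr$labels, classes)
  yva <- match(va$labels, classes)
  if (length(unique(ytr)) < 2L) {
    stop_invalid("training partition lost a class; provide more windows")
  }
  w <- sample_weights(tr$labels)
  xtr <- .flatten_windows(tr$windows)
  xva <- .flatten_windows(va$windows)

  attempt <- 0L
  repeat {
    if (attempt > 0L) .reinit_model(model, derive_seed(config$seed, "restart", attempt))
    fit <- .train_once(model, xtr, ytr, xva, yva, w, classes, config, attempt)
    if (max(fit$history$val_f1) >= config$restart_f1 ||
        attempt >= config$max_restarts) {
      fit$restarts <- attempt
      return(fit)
    }
    attempt <- attempt + 1L
  }
}

# draw a fresh initialisation into an existing model
.reinit_model <- function(model, seed) {
  cfg <- model$config
  cfg$seed <- as.integer(seed)
  fresh <- build_model(cfg)
  for (nm in names(fresh$params)) model$params[[nm]]$val <- fresh$params[[nm]]$val
  if (!is.null(model$bn_states)) {
    for (i in seq_along(model$bn_states)) {
      model$bn_states[[i]]$mean <- model$bn_states[[i]]$mean * 0
      model$bn_states[[i]]$var <- model$bn_states[[i]]$var * 0 + 1
    }
  }
  invisible(model)
}

.train_once <- function(model, xtr, ytr, xva, yva, w, classes, config, attempt = 0L) {
  n_tr <- length(ytr)
  params <- model$params
  opt <- adam_init(params)
  lr <- config$lr
  best <- Inf
  best_epoch <- 0L
  best_snap <- .snapshot_params(model)
  stale <- 0L
  stale_anneal <- 0L
  hist <- list()

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- with_seed(derive_seed(config$seed, "epoch", epoch, attempt),
                           sample.int(n_tr, n_tr, replace = TRUE, prob = w))
    n_batches <- ceiling(n_tr / config$batch_size)
    tl <- 0
    for (bi in seq_len(n_batches)) {
      idx <- order_idx[((bi - 1L) * config$batch_size + 1L):
                         min(bi * config$batch_size, n_tr)]
      loss <- ag_ce(.forward_cols(model, xtr, idx, training = TRUE), ytr[idx])
      ag_zero_grads(params)
      ag_backward(loss)
      opt <- adam_step(opt, params, lr)
      tl <- tl + loss$val[1L] * length(idx)
    }
    tl <- tl / n_tr

    ev <- .evaluate(model, xva, yva, length(classes))
    monitor_val <- if (config$monitor == "loss") ev$loss else -ev$f1
    improved <- monitor_val < best - 1e-12
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl,
                                val_loss = ev$loss, val_f1 = ev$f1, lr = lr)
    if (improved) {
      best <- monitor_val
      best_epoch <- epoch
      best_snap <- .snapshot_params(model)
      stale <- 0L
      stale_anneal <- 0L
    } else {
      stale <- stale + 1L
      stale_anneal <- stale_anneal + 1L
      if (stale_anneal >= config$anneal_patience) {
        lr <- lr * config$anneal_factor
        stale_anneal <- 0L
      }
      if (stale >= config$early_stop_patience) break
    }
  }
  .restore_params(model, best_snap)
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch,
       classes = classes)
}

# batched eval-mode loss and macro F1 on a flattened window matrix
.evaluate <- function(model, xflat, y, n_classes, batch = 512L) {
  n <- ncol(xflat)
  loss <- 0
  pred <- integer(n)
  for (s in seq.int(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    logits <- .forward_cols(model, xflat, idx, training = FALSE)
    loss <- loss + ag_ce(logits, y[idx])$val[1L] * length(idx)
    pred[idx] <- max.col(logits$val, ties.method = "first")
  }
  list(loss = loss / n, f1 = f1_score(y, pred, scheme = "macro"))
}

#' Predict labels for a window set
#'
#' If the test windows have a different length than the model's input (a
#' different sampling rate), each window is first linearly resampled to the
#' training length; matching lengths are passed through untouched.
#'
#' @param model A trained `har_model`.
#' @param test_windows A standardized `window_set`.
#' @param classes Label codes in the order used at training time (the
#'   `classes` element returned by [train_model()]); defaults to `0:(K-1)`.
#' @param batch Evaluation batch size.
#' @return Integer vector of predicted label codes.
#' @export
predict_labels <- function(model, test_windows, classes = NULL, batch = 512L) {
  if (dim(test_windows$windows)[3L] != model$config$channels) {
    stop_invalid("channel mismatch: model expects %d, windows have %d",
                 model$config$channels, dim(test_windows$windows)[3L])
  }
  if (is.null(classes)) classes <- seq_len(model$config$n_classes) - 1L
  ws <- resample_window_set(test_windows, model$config$input_len)
  xflat <- .flatten_windows(ws$windows)
  n <- ncol(xflat)
  pred <- integer(n)
  for (s in seq.int(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    logits <- .forward_cols(model, xflat, idx, training = FALSE)
    pred[idx] <- max.col(logits$val, ties.method = "first")
  }
  classes[pred]
}

#' Write a training history to CSV
#' @param fit Result of [train_model()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
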