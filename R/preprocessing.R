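# Standardisation, sliding-window segmentation, class-weighted sampling and
# per-window linear-interpolation resampling — the exact preprocessing used
# for training and testing.

#' Standardise recordings with training statistics only
#'
#' Computes per-channel mean and population standard deviation from the
#' training series alone and applies the same affine transform to both the
#' training series and any held-out series, so no test information leaks into
#' the normalisation.
#'
#' @param train A `recording`, an N x 3 matrix, or a list of either; pooled to
#'   estimate the statistics.
#' @param apply_to Optional series (same forms) transformed with the training
#'   statistics; defaults to `train`.
#' @return List with `series` (the transformed `apply_to`, matching its input
#'   shape) and `stats` (`mean`, `sd`, each length 3).
#' @export
standardize <- function(train, apply_to = train) {
  pool <- .as_series_list(train)
  x <- do.call(rbind, pool)
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
  if (any(sd == 0)) {
    stop_invalid("zero-variance training channel: %s",
                 paste(c("x", "y", "z")[sd == 0], collapse = ", "))
  }
  stats <- list(mean = mu, sd = sd)
  list(series = .apply_stats(apply_to, stats), stats = stats)
}

#' Apply previously computed standardisation statistics
#'
#' @param x A `recording`, matrix, or list of either.
#' @param stats A `stats` element from [standardize()].
#' @return `x` transformed channel-wise to `(x - mean) / sd`.
#' @export
apply_standardization <- function(x, stats) .apply_stats(x, stats)

.as_series_list <- function(x) {
  if (inherits(x, "recording")) return(list(x$samples))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) {
    return(lapply(x, function(e) if (inherits(e, "recording")) e$samples else as.matrix(e)))
  }
  stop_invalid("expected a recording, a matrix, or a list of them")
}

.apply_stats <- function(x, stats) {
  tf <- function(m) sweep(sweep(m, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  if (inherits(x, "recording")) {
    x$samples <- tf(x$samples)
    return(x)
  }
  if (is.matrix(x)) return(tf(x))
  if (is.list(x)) return(lapply(x, .apply_stats, stats = stats))
  stop_invalid("expected a recording, a matrix, or a list of them")
}

#' Segment a series into fixed-length sliding windows
#'
#' Windows are half-open, 0-based sample ranges `[s, s + L)` starting at
#' `0, step, 2 step, ...`. Each window's label is the majority of its sample
#' labels, with ties resolved to the not-walking class (0).
#'
#' @param series N x 3 matrix (or `recording`; then `labels`/`rate_hz` are
#'   taken from it).
#' @param labels Integer per-sample labels.
#' @param rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds (default 2 s).
#' @param step_s Hop between window starts in seconds (default 1 s, i.e. 50%
#'   overlap).
#' @param subject_id,sensor_code Provenance carried into the window set.
#' @return A `window_set`: list with `windows` (W x L x 3 array), `labels`,
#'   `subject_ids`, `sensor_code`, `rate_hz`, `norm_stats`.
#' @export
make_windows <- function(series, labels = NULL, rate_hz = NULL, window_s = 2,
                         step_s = 1, subject_id = NA_integer_,
                         sensor_code = NA_character_) {
  if (inherits(series, "recording")) {
    if (is.null(labels)) labels <- series$labels
    if (is.null(rate_hz)) rate_hz <- series$rate_hz
    if (is.na(subject_id)) subject_id <- series$subject_id
    if (is.na(sensor_code)) sensor_code <- series$sensor$code
    series <- series$samples
  }
  stopifnot(!is.null(labels), !is.null(rate_hz))
  series <- as.matrix(series)
  n <- nrow(series)
  len <- as.integer(round(window_s * rate_hz))
  step <- max(1L, as.integer(round(step_s * rate_hz)))
  if (n < len) {
    warning("series shorter than one window; returning an empty window set")
    return(.window_set(array(0, c(0L, len, ncol(series))), integer(), integer(),
                       sensor_code, rate_hz))
  }
  starts <- seq.int(0L, n - len, by = step)
  w <- length(starts)
  windows <- array(0, c(w, len, ncol(series)))
  wlab <- integer(w)
  for (i in seq_len(w)) {
    idx <- (starts[i] + 1L):(starts[i] + len)
    windows[i, , ] <- series[idx, ]
    wlab[i] <- .majority_label(labels[idx])
  }
  .window_set(windows, wlab, rep(as.integer(subject_id), w), sensor_code, rate_hz)
}

.majority_label <- function(lab) {
  tab <- table(lab)
  mx <- max(tab)
  winners <- as.integer(names(tab)[tab == mx])
  if (length(winners) > 1L) 0L else winners
}

.window_set <- function(windows, labels, subject_ids, sensor_code, rate_hz,
                        norm_stats = NULL) {
  structure(
    list(windows = windows, labels = as.integer(labels),
         subject_ids = as.integer(subject_ids), sensor_code = sensor_code,
         rate_hz = rate_hz, norm_stats = norm_stats),
    class = "window_set"
  )
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects with matching window length.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "window_set")) sets <- sets[[1L]]
  lens <- vapply(sets, function(s) dim(s$windows)[2L], 0L)
  if (length(unique(lens)) != 1L) stop_invalid("window lengths differ: %s",
                                               paste(unique(lens), collapse = ", "))
  ws <- do.call(abind_first, lapply(sets, function(s) s$windows))
  .window_set(ws, unlist(lapply(sets, function(s) s$labels)),
              unlist(lapply(sets, function(s) s$subject_ids)),
              sets[[1L]]$sensor_code, sets[[1L]]$rate_hz, sets[[1L]]$norm_stats)
}

# bind 3-d arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], 0L))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[(at + 1L):(at + k), , ] <- a
    at <- at + k
  }
  out
}

#' Linearly resample one window to a target length
#'
#' Channel-wise linear interpolation on the normalised time axis `[0, 1]`;
#' endpoints are preserved exactly and no frequency filtering is applied.
#'
#' @param window L_in x C matrix.
#' @param target_len Output length (>= 2).
#' @return `target_len` x C matrix.
#' @export
resample_window <- function(window, target_len) {
  window <- as.matrix(window)
  if (target_len < 2L) stop_invalid("target_len must be >= 2, got %d", target_len)
  l_in <- nrow(window)
  if (l_in < 2L) stop_invalid("window must have at least 2 samples")
  if (l_in == target_len) return(window)
  xin <- seq(0, 1, length.out = l_in)
  xout <- seq(0, 1, length.out = target_len)
  apply(window, 2L, function(ch) stats::approx(xin, ch, xout)$y)
}

#' Resample every window in a window set
#'
#' @param ws A `window_set`.
#' @param target_len Target window length in samples.
#' @return A `window_set` with windows of length `target_len`.
#' @export
resample_window_set <- function(ws, target_len) {
  d <- dim(ws$windows)
  if (d[2L] == target_len) return(ws)
  out <- array(0, c(d[1L], target_len, d[3L]))
  for (i in seq_len(d[1L])) {
    out[i, , ] <- resample_window(ws$windows[i, , ], target_len)
  }
  ws$windows <- out
  ws
}

#' Inverse-frequency sampling weights
#'
#' Weight proportional to the inverse frequency of each window's class, so a
#' weighted sampler draws classes in equal expected proportion.
#'
#' @param labels Integer window labels.
#' @return Numeric weights, one per window, normalised to mean 1.
#' @export
sample_weights <- function(labels) {
  labels <- as.integer(labels)
  tab <- table(labels)
  w <- 1 / as.numeric(tab[as.character(labels)])
  w / mean(w)
}

#' Shuffled train/validation split of a window set
#'
#' @param windows A `window_set` with at least 10 windows.
#' @param ratio Fraction held out for validation (default 0.1, the 9:1 split).
#' @param seed Integer seed; the index partition is deterministic given it.
#' @return List with `train` and `val` window sets.
#' @export
split_train_val <- function(windows, ratio = 0.1, seed = 1L) {
  w <- length(windows$labels)
  if (w < 10L) stop_invalid("need at least 10 windows to split, got %d", w)
  n_val <- as.integer(round(ratio * w))
  perm <- with_seed(seed, sample.int(w))
  val_idx <- sort(perm[seq_len(n_val)])
  train_idx <- sort(perm[-seq_len(n_val)])
  list(train = .subset_windows(windows, train_idx),
       val = .subset_windows(windows, val_idx))
}

.subset_windows <- function(ws, idx) {
  .window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
              ws$subject_ids[idx], ws$sensor_code, ws$rate_hz, ws$norm_stats)
}

#' Write a window set as a binary blob plus JSON sidecar
#'
#' @param ws A `window_set`.
#' @param path Output path for the binary file; a `.json` sidecar with shape,
#'   rate and normalisation statistics is written next to it.
#' @return Invisibly, `path`.
#' @export
write_window_set <- function(ws, path) {
  saveRDS(ws, path, compress = "gzip")
  sidecar <- list(shape = dim(ws$windows), rate_hz = ws$rate_hz,
                  sensor_code = ws$sensor_code,
                  n_windows = length(ws$labels),
                  classes = as.list(table(ws$labels)),
                  norm_stats = ws$norm_stats)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a window set written by [write_window_set()]
#' @param path Path passed to [write_window_set()].
#' @return The `window_set`.
#' @export
read_window_set <- function(path) readRDS(path)

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of %d samples x %d channels @ %g Hz (%s)\n",
              d[1L], d[2L], d[3L], x$rate_hz,
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}
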