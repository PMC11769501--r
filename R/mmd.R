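# Distribution-shift quantification with a multiscale-kernel Maximum Mean
# Discrepancy (MMD), estimated iteratively on random contiguous 100-sample
# windows so arbitrarily long recordings stay tractable.

#' MMD estimation configuration
#'
#' @param bandwidths Positive kernel bandwidths of the multiscale kernel.
#'   The default list spans sub-unit to unit scales appropriate for
#'   standardized (z-scored) accelerometer samples.
#' @param window_samples Number of consecutive samples per random window.
#' @param iterations Number of random window pairs averaged.
#' @param seed Integer seed for the window draws.
#' @param estimator `"biased"` (V-statistic, non-negative) or `"unbiased"`
#'   (U-statistic).
#' @return An `mmd_config` list.
#' @export
mmd_config <- function(bandwidths = c(0.2, 0.5, 0.9, 1.3, 1.5, 1.6),
                       window_samples = 100L, iterations = 50000L,
                       seed = 1L, estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  if (length(bandwidths) == 0L || any(bandwidths <= 0)) {
    stop_invalid("bandwidths must be a non-empty positive vector")
  }
  if (window_samples < 2L) stop_invalid("window_samples must be >= 2")
  if (iterations < 1L) stop_invalid("iterations must be >= 1")
  structure(list(bandwidths = bandwidths,
                 window_samples = as.integer(window_samples),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 estimator = estimator),
            class = "mmd_config")
}

#' Multiscale kernel from squared distances
#'
#' `k(d^2) = sum_a a^4 / (a^2 + d^2)` over the bandwidth list `a` — a
#' rational-quadratic multiscale family in which each scale contributes with
#' weight `a^2`, so at zero distance the kernel equals the sum of squared
#' bandwidths (7.60 for the default list).
#'
#' @param sq_dists Matrix (or vector) of squared Euclidean distances (>= 0).
#' @param bandwidths Positive bandwidths.
#' @return Kernel values, same shape as `sq_dists`.
#' @export
multiscale_kernel <- function(sq_dists,
                              bandwidths = c(0.2, 0.5, 0.9, 1.3, 1.5, 1.6)) {
  if (any(sq_dists < 0)) stop_invalid("squared distances must be non-negative")
  out <- 0
  for (a in bandwidths) {
    a2 <- a * a
    out <- out + a2 * a2 / (a2 + sq_dists)
  }
  out
}

# pairwise squared Euclidean distances between rows of x and y
.sq_dists <- function(x, y) {
  xx <- rowSums(x^2)
  yy <- rowSums(y^2)
  d <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
  d[d < 0] <- 0
  d
}

#' Squared MMD between two point sets
#'
#' Biased V-statistic `mean(K_XX) + mean(K_YY) - 2 mean(K_XY)` with the
#' multiscale kernel (the study's "MMD value"); the unbiased U-statistic
#' drops the diagonal terms.
#'
#' @param x,y Point sets as `n x d` / `m x d` matrices (same `d`).
#' @param config An [mmd_config()]; only `bandwidths` and `estimator` are
#'   used.
#' @return Scalar MMD^2 estimate (non-negative for the biased estimator).
#' @export
mmd_squared <- function(x, y, config = mmd_config()) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) {
    stop_invalid("dimension mismatch: x has %d columns, y has %d", ncol(x), ncol(y))
  }
  if (nrow(x) < 2L || nrow(y) < 2L) stop_invalid("need at least 2 points per set")
  kxx <- multiscale_kernel(.sq_dists(x, x), config$bandwidths)
  kyy <- multiscale_kernel(.sq_dists(y, y), config$bandwidths)
  kxy <- multiscale_kernel(.sq_dists(x, y), config$bandwidths)
  if (config$estimator == "biased") {
    mean(kxx) + mean(kyy) - 2 * mean(kxy)
  } else {
    n <- nrow(x); m <- nrow(y)
    (sum(kxx) - sum(diag(kxx))) / (n * (n - 1)) +
      (sum(kyy) - sum(diag(kyy))) / (m * (m - 1)) - 2 * mean(kxy)
  }
}

#' Iterative MMD between two long series
#'
#' Each iteration draws one contiguous window of `window_samples` consecutive
#' rows at a uniformly random start from each series (every time step is one
#' d-dimensional observation), computes the squared MMD between the two
#' window point sets, and the final value is the mean over iterations.
#' Deterministic given `config$seed`.
#'
#' @param series_a,series_b Numeric matrices (rows = time steps).
#' @param config An [mmd_config()].
#' @return List with `value` (mean MMD), `se` (standard error of the
#'   iteration mean), `n_iterations`.
#' @export
iterative_mmd <- function(series_a, series_b, config = mmd_config()) {
  series_a <- as.matrix(series_a)
  series_b <- as.matrix(series_b)
  ws <- config$window_samples
  if (nrow(series_a) < ws) {
    stop_invalid("series_a has %d rows, shorter than window_samples = %d",
                 nrow(series_a), ws)
  }
  if (nrow(series_b) < ws) {
    stop_invalid("series_b has %d rows, shorter than window_samples = %d",
                 nrow(series_b), ws)
  }
  na <- nrow(series_a) - ws + 1L
  nb <- nrow(series_b) - ws + 1L
  vals <- with_seed(config$seed, {
    starts_a <- sample.int(na, config$iterations, replace = TRUE)
    starts_b <- sample.int(nb, config$iterations, replace = TRUE)
    vapply(seq_len(config$iterations), function(i) {
      wa <- series_a[starts_a[i]:(starts_a[i] + ws - 1L), , drop = FALSE]
      wb <- series_b[starts_b[i]:(starts_b[i] + ws - 1L), , drop = FALSE]
      mmd_squared(wa, wb, config)
    }, 0)
  })
  list(value = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_iterations = length(vals))
}

#' Exhaustive-enumeration MMD for short series
#'
#' Averages the squared MMD over *all* window-start pairs; the exact value
#' the random-iteration estimator converges to. Intended for short series.
#'
#' @inheritParams iterative_mmd
#' @return Scalar exact mean MMD over all start pairs.
#' @export
enumerate_mmd <- function(series_a, series_b, config = mmd_config()) {
  series_a <- as.matrix(series_a)
  series_b <- as.matrix(series_b)
  ws <- config$window_samples
  na <- nrow(series_a) - ws + 1L
  nb <- nrow(series_b) - ws + 1L
  if (na < 1L || nb < 1L) stop_invalid("series shorter than window_samples")
  tot <- 0
  for (i in seq_len(na)) {
    wa <- series_a[i:(i + ws - 1L), , drop = FALSE]
    for (j in seq_len(nb)) {
      wb <- series_b[j:(j + ws - 1L), , drop = FALSE]
      tot <- tot + mmd_squared(wa, wb, config)
    }
  }
  tot / (na * nb)
}

#' Per-class iterative MMD between a training and a testing side
#'
#' Restricts both sides to each requested class (concatenating that class's
#' segments), runs [iterative_mmd()] per class, and averages over classes.
#' Classes missing (or shorter than one window) on either side are excluded
#' from the mean with a warning.
#'
#' @param train_series,test_series Numeric matrices (rows = time steps),
#'   typically standardized with the training statistics.
#' @param train_labels,test_labels Integer per-row class codes.
#' @param classes_to_use Class codes to evaluate (e.g. `1` for the walking
#'   class of the binary task). Null/negative classes should simply not be
#'   listed.
#' @param config An [mmd_config()].
#' @return An `mmd_result`: list with `per_class` (named numeric), `mean`,
#'   `per_class_se`, `n_iterations_used`.
#' @export
per_class_mmd <- function(train_series, train_labels, test_series, test_labels,
                          classes_to_use = 1L, config = mmd_config()) {
  train_series <- as.matrix(train_series)
  test_series <- as.matrix(test_series)
  stopifnot(nrow(train_series) == length(train_labels),
            nrow(test_series) == length(test_labels))
  per <- c()
  ses <- c()
  used <- 0L
  for (cl in classes_to_use) {
    a <- train_series[train_labels == cl, , drop = FALSE]
    b <- test_series[test_labels == cl, , drop = FALSE]
    if (nrow(a) < config$window_samples || nrow(b) < config$window_samples) {
      warning(sprintf("class %s has fewer than %d samples on one side; excluded",
                      cl, config$window_samples))
      per[as.character(cl)] <- NA_real_
      ses[as.character(cl)] <- NA_real_
      next
    }
    sub <- config
    sub$seed <- derive_seed(config$seed, "class", cl)
    r <- iterative_mmd(a, b, sub)
    per[as.character(cl)] <- r$value
    ses[as.character(cl)] <- r$se
    used <- used + r$n_iterations
  }
  structure(list(per_class = per, mean = mean(per, na.rm = TRUE),
                 per_class_se = ses, n_iterations_used = used),
            class = "mmd_result")
}

#' @export
print.mmd_result <- function(x, ...) {
  cat(sprintf("<mmd_result> mean MMD %.4f over %d class(es)\n",
              x$mean, sum(!is.na(x$per_class))))
  invisible(x)
}
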