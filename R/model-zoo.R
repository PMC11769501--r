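# The three hybrid CNN-recurrent HAR architectures, implemented on the
# package's autodiff engine with exact trainable-parameter accounting.
#
# All three share the same front end: four 1-D convolution layers along time
# (kernel 5, stride 2) applied per accelerometer channel with shared weights
# (kernel footprint 5x1), so channel features are kept separate until the
# recurrent stage.
#
# deepconvlstm: convs (64 filters) -> channel features concatenated -> one
#   LSTM layer of 128 cells (separate input and recurrent bias vectors) ->
#   linear head on the final step.
# tinyhar: convs (20 filters, each followed by batch normalisation) ->
#   cross-channel self-attention (q/k/v 20->20 without biases, gated
#   residual) -> fully connected cross-channel fusion (60 -> 40) -> LSTM of
#   40 cells -> gated temporal attention (fc 40->40 + tanh, score fc 40->1
#   without bias) -> linear head.
# attend_discriminate: convs (64 filters) -> cross-channel self-attention
#   (q/k/v 64->64 without biases, gated residual) -> two stacked GRU layers
#   of 128 cells -> temporal attention (score fc 128->1) -> linear head.
#
# These readings reproduce the reference trainable-parameter counts exactly:
# 227,138 / 24,864 / 297,412 for 3 input channels and 2 classes, independent
# of the input length.

.conv_kernel <- 5L
.conv_stride <- 2L
.n_conv_layers <- 4L
.gate_init <- 0.1

.archs <- c("deepconvlstm", "tinyhar", "attend_discriminate")

#' Configure a HAR model
#'
#' @param arch One of `"deepconvlstm"`, `"tinyhar"`, `"attend_discriminate"`.
#' @param input_len Window length in samples (e.g. 128 for 64 Hz or 200 for
#'   100 Hz two-second windows).
#' @param n_classes Number of activity classes (>= 2).
#' @param channels Number of input channels (3 for a tri-axial accelerometer).
#' @param seed Integer seed for weight initialisation.
#' @return A `model_config` list.
#' @export
model_config <- function(arch = .archs, input_len = 128L, n_classes = 2L,
                         channels = 3L, seed = 1L) {
  arch <- match.arg(arch)
  if (n_classes < 2L) stop_invalid("n_classes must be >= 2")
  min_len <- .min_input_len()
  if (input_len < min_len) {
    stop_invalid("input_len %d too small for %d stride-%d convolutions; minimum is %d",
                 input_len, .n_conv_layers, .conv_stride, min_len)
  }
  structure(list(arch = arch, input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes),
                 channels = as.integer(channels), seed = as.integer(seed)),
            class = "model_config")
}

.min_input_len <- function() {
  l <- 1L
  for (i in seq_len(.n_conv_layers)) l <- (l - 1L) * .conv_stride + .conv_kernel
  l
}

# time-length sequence through the conv stack
.conv_lens <- function(input_len) {
  out <- integer(.n_conv_layers)
  l <- as.integer(input_len)
  for (i in seq_len(.n_conv_layers)) {
    l <- (l - .conv_kernel) %/% .conv_stride + 1L
    out[i] <- l
  }
  out
}

.init_mat <- function(nr, nc, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

.bn_state <- function(f) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, f)
  e$var <- rep(1, f)
  e$momentum <- 0.1
  e
}

#' Build a model from a configuration
#'
#' @param config A [model_config()].
#' @return A `har_model` whose forward pass maps a `batch x input_len x
#'   channels` array to `batch x n_classes` scores (see [model_forward()]).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    switch(config$arch,
      deepconvlstm = .build_dcl(config),
      tinyhar = .build_tinyhar(config),
      attend_discriminate = .build_ad(config)
    )
  })
}

.conv_params <- function(filters) {
  p <- list()
  p[["conv1_w"]] <- ag_param(.init_mat(.conv_kernel, filters, .conv_kernel))
  p[["conv1_b"]] <- ag_param(matrix(0, 1L, filters))
  for (l in 2:.n_conv_layers) {
    fin <- .conv_kernel * filters
    p[[sprintf("conv%d_w", l)]] <- ag_param(.init_mat(fin, filters, fin))
    p[[sprintf("conv%d_b", l)]] <- ag_param(matrix(0, 1L, filters))
  }
  p
}

.lstm_params <- function(input_dim, hidden) {
  k <- hidden
  list(
    wx = ag_param(.init_mat(input_dim, 4L * hidden, k)),
    wh = ag_param(.init_mat(hidden, 4L * hidden, k)),
    bi = ag_param(matrix(0, 1L, 4L * hidden)),
    bh = ag_param(matrix(0, 1L, 4L * hidden))
  )
}

.gru_params <- function(input_dim, hidden) {
  k <- hidden
  list(
    wx = ag_param(.init_mat(input_dim, 3L * hidden, k)),
    wh = ag_param(.init_mat(hidden, 3L * hidden, k)),
    bi = ag_param(matrix(0, 1L, 3L * hidden)),
    bh = ag_param(matrix(0, 1L, 3L * hidden))
  )
}

.build_dcl <- function(config) {
  f <- 64L
  h <- 128L
  p <- .conv_params(f)
  lstm <- .lstm_params(config$channels * f, h)
  p$lstm_wx <- lstm$wx; p$lstm_wh <- lstm$wh
  p$lstm_bi <- lstm$bi; p$lstm_bh <- lstm$bh
  p$head_w <- ag_param(.init_mat(h, config$n_classes, h))
  p$head_b <- ag_param(matrix(0, 1L, config$n_classes))
  .har_model(config, p, filters = f, hidden = h)
}

.build_tinyhar <- function(config) {
  f <- 20L
  h <- 2L * f
  p <- .conv_params(f)
  for (l in seq_len(.n_conv_layers)) {
    p[[sprintf("bn%d_g", l)]] <- ag_param(matrix(1, 1L, f))
    p[[sprintf("bn%d_b", l)]] <- ag_param(matrix(0, 1L, f))
  }
  p$attn_q <- ag_param(.init_mat(f, f, f))
  p$attn_k <- ag_param(.init_mat(f, f, f))
  p$attn_v <- ag_param(.init_mat(f, f, f))
  p$attn_gamma <- ag_param(matrix(.gate_init, 1L, 1L))
  p$fuse_w <- ag_param(.init_mat(config$channels * f, h, config$channels * f))
  p$fuse_b <- ag_param(matrix(0, 1L, h))
  lstm <- .lstm_params(h, h)
  p$lstm_wx <- lstm$wx; p$lstm_wh <- lstm$wh
  p$lstm_bi <- lstm$bi; p$lstm_bh <- lstm$bh
  p$tattn_w1 <- ag_param(.init_mat(h, h, h))
  p$tattn_b1 <- ag_param(matrix(0, 1L, h))
  p$tattn_w2 <- ag_param(.init_mat(h, 1L, h))
  p$tattn_gamma <- ag_param(matrix(.gate_init, 1L, 1L))
  p$head_w <- ag_param(.init_mat(h, config$n_classes, h))
  p$head_b <- ag_param(matrix(0, 1L, config$n_classes))
  bn <- lapply(seq_len(.n_conv_layers), function(i) .bn_state(f))
  .har_model(config, p, filters = f, hidden = h, bn_states = bn)
}

.build_ad <- function(config) {
  f <- 64L
  h <- 128L
  p <- .conv_params(f)
  p$attn_q <- ag_param(.init_mat(f, f, f))
  p$attn_k <- ag_param(.init_mat(f, f, f))
  p$attn_v <- ag_param(.init_mat(f, f, f))
  p$attn_gamma <- ag_param(matrix(.gate_init, 1L, 1L))
  gru1 <- .gru_params(config$channels * f, h)
  p$gru1_wx <- gru1$wx; p$gru1_wh <- gru1$wh
  p$gru1_bi <- gru1$bi; p$gru1_bh <- gru1$bh
  gru2 <- .gru_params(h, h)
  p$gru2_wx <- gru2$wx; p$gru2_wh <- gru2$wh
  p$gru2_bi <- gru2$bi; p$gru2_bh <- gru2$bh
  p$tattn_w <- ag_param(.init_mat(h, 1L, h))
  p$tattn_b <- ag_param(matrix(0, 1L, 1L))
  p$head_w <- ag_param(.init_mat(h, config$n_classes, h))
  p$head_b <- ag_param(matrix(0, 1L, config$n_classes))
  .har_model(config, p, filters = f, hidden = h)
}

.har_model <- function(config, params, filters, hidden, bn_states = NULL) {
  structure(list(config = config, params = params, filters = filters,
                 hidden = hidden, bn_states = bn_states),
            class = "har_model")
}

#' Count trainable parameters
#'
#' @param model A `har_model`.
#' @return Exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), 0))
}

## ---- forward passes --------------------------------------------------------

# shared conv stack; x_node rows ordered ((b, ch), t), single feature column
.conv_forward <- function(model, x_node, input_len, training) {
  p <- model$params
  t_in <- as.integer(input_len)
  f_in <- 1L
  h <- x_node
  for (l in seq_len(.n_conv_layers)) {
    h <- ag_conv1d(h, p[[sprintf("conv%d_w", l)]], p[[sprintf("conv%d_b", l)]],
                   t_in, .conv_kernel, .conv_stride)
    t_in <- (t_in - .conv_kernel) %/% .conv_stride + 1L
    if (!is.null(model$bn_states)) {
      h <- ag_bnorm(h, p[[sprintf("bn%d_g", l)]], p[[sprintf("bn%d_b", l)]],
                    model$bn_states[[l]], training)
    }
    h <- ag_relu(h)
    f_in <- model$filters
  }
  list(node = h, t_out = t_in)
}

# channel-c row indices in a ((b, ch), t) matrix, output in step-major order
# (all of step 1 first), matching the fused recurrent layout
.chan_idx <- function(b, c_total, tp, ch) {
  as.vector(outer(((seq_len(b) - 1L) * c_total + (ch - 1L)) * tp,
                  seq_len(tp), "+"))
}

# rows of step t in a step-major (n_steps * batch) x d matrix
.step_rows <- function(b, t) ((t - 1L) * b + 1L):(t * b)

# gated cross-channel self-attention; returns refined per-channel matrices
.chan_attention <- function(x_chans, wq, wk, wv, gamma, scale) {
  qs <- lapply(x_chans, ag_matmul, b = wq)
  ks <- lapply(x_chans, ag_matmul, b = wk)
  vs <- lapply(x_chans, ag_matmul, b = wv)
  c_total <- length(x_chans)
  lapply(seq_len(c_total), function(i) {
    scores <- lapply(seq_len(c_total), function(j) {
      ag_caffine(ag_dotrows(qs[[i]], ks[[j]]), scale)
    })
    a <- ag_softmax(ag_cbind(scores))
    ctx <- NULL
    for (j in seq_len(c_total)) {
      term <- ag_mulcol(vs[[j]], ag_cols(a, j))
      ctx <- if (is.null(ctx)) term else ag_add(ctx, term)
    }
    ag_add(x_chans[[i]], ag_smul(ctx, gamma))
  })
}

#' Run a model forward
#'
#' @param model A `har_model`.
#' @param x Array `batch x input_len x channels` (a single window may be
#'   passed as `input_len x channels`).
#' @param training Logical; enables batch-statistics mode of normalisation
#'   layers and gradient tracking.
#' @return The autodiff node of the class scores (`batch x n_classes`);
#'   use `$val` for the numeric matrix.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  if (d[2L] != model$config$input_len) {
    stop_invalid("model expects input_len %d, got windows of length %d",
                 model$config$input_len, d[2L])
  }
  if (d[3L] != model$config$channels) {
    stop_invalid("model expects %d channels, got %d", model$config$channels, d[3L])
  }
  .forward_core(model, matrix(aperm(x, c(2L, 3L, 1L)), ncol = 1L), d[1L],
                training)
}

# windows flattened once into a (input_len * channels) x n_windows matrix;
# column-major flattening puts each window's samples in (time, channel) order
.flatten_windows <- function(x) {
  matrix(aperm(x, c(2L, 3L, 1L)), ncol = dim(x)[1L])
}

# forward selected columns of a flattened window matrix
.forward_cols <- function(model, xflat, idx, training = FALSE) {
  .forward_core(model, matrix(xflat[, idx, drop = FALSE], ncol = 1L),
                length(idx), training)
}

.forward_core <- function(model, m0, b, training = FALSE) {
  p <- model$params
  c_total <- model$config$channels
  x0 <- ag_const(m0)
  conv <- .conv_forward(model, x0, model$config$input_len, training)
  tp <- conv$t_out
  m <- conv$node

  if (model$config$arch == "deepconvlstm") {
    x_seq <- ag_cbind(lapply(seq_len(c_total), function(ch) {
      ag_rows(m, .chan_idx(b, c_total, tp, ch))
    }))
    hseq <- ag_lstm_seq(x_seq, p$lstm_wx, p$lstm_wh, p$lstm_bi, p$lstm_bh, tp)
    out <- ag_rows(hseq, .step_rows(b, tp))
  } else if (model$config$arch == "tinyhar") {
    x_chans <- lapply(seq_len(c_total), function(ch) {
      ag_rows(m, .chan_idx(b, c_total, tp, ch))
    })
    refined <- .chan_attention(x_chans, p$attn_q, p$attn_k, p$attn_v,
                               p$attn_gamma, 1 / sqrt(model$filters))
    fused <- ag_relu(ag_bias(ag_matmul(ag_cbind(refined), p$fuse_w), p$fuse_b))
    hseq <- ag_lstm_seq(fused, p$lstm_wx, p$lstm_wh, p$lstm_bi, p$lstm_bh, tp)
    hs <- lapply(seq_len(tp), function(t) ag_rows(hseq, .step_rows(b, t)))
    scores <- lapply(hs, function(h) {
      ag_matmul(ag_tanh(ag_bias(ag_matmul(h, p$tattn_w1), p$tattn_b1)), p$tattn_w2)
    })
    a <- ag_softmax(ag_cbind(scores))
    ctx <- NULL
    for (t in seq_len(tp)) {
      term <- ag_mulcol(hs[[t]], ag_cols(a, t))
      ctx <- if (is.null(ctx)) term else ag_add(ctx, term)
    }
    out <- ag_add(hs[[tp]], ag_smul(ctx, p$tattn_gamma))
  } else {
    x_chans <- lapply(seq_len(c_total), function(ch) {
      ag_rows(m, .chan_idx(b, c_total, tp, ch))
    })
    refined <- .chan_attention(x_chans, p$attn_q, p$attn_k, p$attn_v,
                               p$attn_gamma, 1 / sqrt(model$filters))
    x_seq <- ag_cbind(refined)
    h1 <- ag_gru_seq(x_seq, p$gru1_wx, p$gru1_wh, p$gru1_bi, p$gru1_bh, tp)
    h2seq <- ag_gru_seq(h1, p$gru2_wx, p$gru2_wh, p$gru2_bi, p$gru2_bh, tp)
    h2 <- lapply(seq_len(tp), function(t) ag_rows(h2seq, .step_rows(b, t)))
    scores <- lapply(h2, function(h) ag_bias(ag_matmul(h, p$tattn_w), p$tattn_b))
    a <- ag_softmax(ag_cbind(scores))
    ctx <- NULL
    for (t in seq_len(tp)) {
      term <- ag_mulcol(h2[[t]], ag_cols(a, t))
      ctx <- if (is.null(ctx)) term else ag_add(ctx, term)
    }
    out <- ctx
  }
  ag_bias(ag_matmul(out, p$head_w), p$head_b)
}

#' Count multiply-accumulate operations for one forward pass
#'
#' One MAC per multiply-accumulate in convolutions, linear maps, recurrent
#' matrix products and attention score/value products; activations and
#' normalisations are excluded.
#'
#' @param model A `har_model`.
#' @param input_len Window length in samples; defaults to the model's
#'   configured length.
#' @return MAC count for a single window.
#' @export
count_macs <- function(model, input_len = model$config$input_len) {
  cfg <- model$config
  c_total <- cfg$channels
  f <- model$filters
  h <- model$hidden
  lens <- .conv_lens(input_len)
  tp <- lens[.n_conv_layers]
  conv <- c_total * lens[1L] * .conv_kernel * 1L * f +
    sum(c_total * lens[-1L] * .conv_kernel * f * f)
  attn <- function(dim_f) {
    tp * (c_total * 3 * dim_f * dim_f +  # q, k, v projections
            c_total * c_total * dim_f +  # score dot products
            c_total * c_total * dim_f)   # attention-weighted value sum
  }
  switch(cfg$arch,
    deepconvlstm = conv + tp * 4 * (c_total * f * h + h * h) + h * cfg$n_classes,
    tinyhar = conv + attn(f) + tp * c_total * f * h +            # fusion
      tp * 4 * (h * h + h * h) +                                 # LSTM
      tp * (h * h + h) + h +                                     # temporal attention
      h * cfg$n_classes,
    attend_discriminate = conv + attn(f) +
      tp * 3 * (c_total * f * h + h * h) + tp * 3 * (h * h + h * h) +
      tp * h +                                                   # temporal scores
      tp * h +                                                   # weighted sum
      h * cfg$n_classes
  )
}

#' Save model weights and configuration
#'
#' Weights go into a single serialized file; the configuration is written as
#' a JSON sidecar.
#'
#' @param model A `har_model`.
#' @param path Output path for the weights file.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  weights <- lapply(model$params, function(p) p$val)
  bn <- if (!is.null(model$bn_states)) {
    lapply(model$bn_states, function(s) list(mean = s$mean, var = s$var))
  }
  saveRDS(list(config = unclass(model$config), weights = weights, bn = bn), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved with [save_model()]
#' @param path Path passed to [save_model()].
#' @return A `har_model`.
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfg <- do.call(model_config, blob$config)
  model <- build_model(cfg)
  for (nm in names(blob$weights)) model$params[[nm]]$val <- blob$weights[[nm]]
  if (!is.null(blob$bn)) {
    for (i in seq_along(blob$bn)) {
      model$bn_states[[i]]$mean <- blob$bn[[i]]$mean
      model$bn_states[[i]]$var <- blob$bn[[i]]$var
    }
  }
  model
}

# deep-copy / restore of parameter values (used for best-epoch checkpoints)
.snapshot_params <- function(model) lapply(model$params, function(p) p$val)
.restore_params <- function(model, snap) {
  for (nm in names(snap)) model$params[[nm]]$val <- snap[[nm]]
  invisible(model)
}

#' Architecture complexity report
#'
#' @param arch Architecture name.
#' @param input_len Window length in samples.
#' @param n_classes,channels Passed to [model_config()].
#' @return List with `trainable_parameters` and `macs_per_window`.
#' @export
complexity_report <- function(arch, input_len = 128L, n_classes = 2L,
                              channels = 3L) {
  model <- build_model(model_config(arch, input_len, n_classes, channels))
  list(arch = arch, input_len = as.integer(input_len),
       trainable_parameters = count_parameters(model),
       macs_per_window = count_macs(model))
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s: input %d x %d, %d classes, %s parameters\n",
              x$config$arch, x$config$input_len, x$config$channels,
              x$config$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
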