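# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value is a node: an environment holding `val` (a base-R matrix),
# `grad` (accumulated cotangent, same shape), `parents` and a `backfn`
# closure returning one gradient per parent. The graph is built eagerly;
# ag_backward() runs a depth-first topological sort and pulls gradients
# back to the leaves. Only what the three HAR architectures need is
# implemented; all operators are gradient-checked against finite
# differences in the test suite.

.ag_env <- new.env(parent = emptyenv())
.ag_env$id <- 0L

ag_node <- function(val, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$is_param <- FALSE
  .ag_env$id <- .ag_env$id + 1L
  n$id <- .ag_env$id
  class(n) <- "ag_node"
  n
}

ag_const <- function(val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  ag_node(val)
}

ag_param <- function(val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  n <- ag_node(val)
  n$is_param <- TRUE
  n
}

# Topologically ordered list of nodes reachable from `root`. Visited nodes
# are marked with an integer stamp stored on the node itself (string keys
# would intern one string per node in R's permanent CHARSXP cache).
ag_toposort <- function(root) {
  stamp <- (.ag_env$stamp <- (.ag_env$stamp %||% 0L) + 1L)
  order <- vector("list", 256L)
  n_out <- 0L
  # iterative DFS with explicit stack; entries: list(node, child index)
  stack <- list(list(node = root, i = 0L))
  root$.seen <- stamp
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      if (!identical(p$.seen, stamp)) {
        p$.seen <- stamp
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      n_out <- n_out + 1L
      if (n_out > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_out]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  order[seq_len(n_out)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backpropagate from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  order <- ag_toposort(loss)
  loss$grad <- matrix(1, 1L, 1L)
  for (k in rev(seq_along(order))) {
    node <- order[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- operators -------------------------------------------------------------

# fast row-broadcasts (x: N x F, v: length F)
.addrow <- function(x, v) x + matrix(v, nrow(x), ncol(x), byrow = TRUE)
.mulrow <- function(x, v) x * matrix(v, nrow(x), ncol(x), byrow = TRUE)

ag_matmul <- function(a, b) {
  ag_node(a$val %*% b$val, list(a, b), function(g) {
    list(tcrossprod(g, b$val), crossprod(a$val, g))
  })
}

ag_add <- function(a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

# x: N x F, b: 1 x F bias broadcast over rows
ag_bias <- function(x, b) {
  ag_node(.addrow(x$val, as.vector(b$val)), list(x, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ag_mul <- function(a, b) {
  stopifnot(all(dim(a$val) == dim(b$val)))
  ag_node(a$val * b$val, list(a, b), function(g) list(g * b$val, g * a$val))
}

# multiply by a 1x1 parameter node (gate)
ag_smul <- function(x, s) {
  ag_node(x$val * s$val[1L], list(x, s), function(g) {
    list(g * s$val[1L], matrix(sum(g * x$val), 1L, 1L))
  })
}

# constant affine transform a*x + c
ag_caffine <- function(x, a, c = 0) {
  ag_node(a * x$val + c, list(x), function(g) list(a * g))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(x) {
  s <- tanh(x$val)
  ag_node(s, list(x), function(g) list(g * (1 - s^2)))
}

ag_relu <- function(x) {
  s <- x$val
  mask <- s > 0
  s[!mask] <- 0
  ag_node(s, list(x), function(g) list(g * mask))
}

# row-wise softmax
ag_softmax <- function(x) {
  m <- x$val - apply(x$val, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ag_node(s, list(x), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

ag_rows <- function(x, idx) {
  idx <- as.integer(idx)
  ag_node(x$val[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    # idx may repeat across calls but is unique within one gather here;
    # use rowsum to stay safe for arbitrary index vectors.
    rs <- rowsum(g, group = idx)
    gx[as.integer(rownames(rs)), ] <- rs
    list(gx)
  })
}

ag_cols <- function(x, idx) {
  idx <- as.integer(idx)
  ag_node(x$val[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[, idx] <- gx[, idx] + g
    list(gx)
  })
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# row-wise dot product -> N x 1
ag_dotrows <- function(a, b) {
  ag_node(matrix(rowSums(a$val * b$val), ncol = 1L), list(a, b), function(g) {
    gv <- as.vector(g)
    list(a$val * 0 + gv * b$val, b$val * 0 + gv * a$val)
  })
}

# scale each row of x (N x F) by w (N x 1)
ag_mulcol <- function(x, w) {
  wv <- as.vector(w$val)
  ag_node(x$val * wv, list(x, w), function(g) {
    list(g * wv, matrix(rowSums(g * x$val), ncol = 1L))
  })
}

# 1-D convolution along time, shared across signals.
# x: (n_signals * t_in) x f_in matrix, rows ordered signal-major, time-minor.
# w: (k * f_in) x f_out with row order (k - 1) * f_in + f. b: 1 x f_out.
ag_conv1d <- function(x, w, b, t_in, k, stride) {
  f_in <- ncol(x$val)
  n_sig <- nrow(x$val) %/% t_in
  stopifnot(n_sig * t_in == nrow(x$val))
  t_out <- (t_in - k) %/% stride + 1L
  stopifnot(t_out >= 1L)
  base <- rep((seq_len(n_sig) - 1L) * t_in, each = t_out) +
    rep((seq_len(t_out) - 1L) * stride, times = n_sig)
  xc <- matrix(0, n_sig * t_out, k * f_in)
  for (kk in seq_len(k)) {
    xc[, ((kk - 1L) * f_in + 1L):(kk * f_in)] <- x$val[base + kk, , drop = FALSE]
  }
  z <- .addrow(xc %*% w$val, as.vector(b$val))
  ag_node(z, list(x, w, b), function(g) {
    gw <- crossprod(xc, g)
    gb <- matrix(colSums(g), 1L)
    gxc <- tcrossprod(g, w$val)
    gx <- matrix(0, nrow(x$val), f_in)
    for (kk in seq_len(k)) {
      rows <- base + kk
      gx[rows, ] <- gx[rows, ] + gxc[, ((kk - 1L) * f_in + 1L):(kk * f_in), drop = FALSE]
    }
    list(gx, gw, gb)
  })
}

# Batch normalisation over rows (per column), with running statistics kept in
# `state` (an environment with mean, var, momentum). In eval mode running
# statistics are treated as constants.
ag_bnorm <- function(x, gamma, beta, state, training, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x$val)
    xc <- .addrow(x$val, -mu)
    v <- colMeans(xc^2)
    n <- nrow(x$val)
    state$mean <- (1 - state$momentum) * state$mean + state$momentum * mu
    # unbiased variance for running stats, population variance in the forward
    state$var <- (1 - state$momentum) * state$var +
      state$momentum * v * n / max(n - 1, 1)
    inv <- 1 / sqrt(v + eps)
    xhat <- .mulrow(xc, inv)
    y <- .addrow(.mulrow(xhat, as.vector(gamma$val)), as.vector(beta$val))
    ag_node(y, list(x, gamma, beta), function(g) {
      gg <- matrix(colSums(g * xhat), 1L)
      gb <- matrix(colSums(g), 1L)
      gxhat <- .mulrow(g, as.vector(gamma$val))
      # standard batch-norm backward
      t1 <- .addrow(gxhat, -colMeans(gxhat))
      t2 <- .mulrow(xhat, colMeans(gxhat * xhat))
      gx <- .mulrow(t1 - t2, inv)
      list(gx, gg, gb)
    })
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- .mulrow(.addrow(x$val, -state$mean), inv)
    y <- .addrow(.mulrow(xhat, as.vector(gamma$val)), as.vector(beta$val))
    ag_node(y, list(x, gamma, beta), function(g) {
      gg <- matrix(colSums(g * xhat), 1L)
      gb <- matrix(colSums(g), 1L)
      gx <- .mulrow(.mulrow(g, as.vector(gamma$val)), inv)
      list(gx, gg, gb)
    })
  }
}

# Mean cross-entropy between logits (N x C) and integer labels y in 1..C.
ag_ce <- function(logits, y) {
  y <- as.integer(y)
  m <- logits$val - apply(logits$val, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ag_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    gy <- p
    gy[cbind(seq_len(n), y)] <- gy[cbind(seq_len(n), y)] - 1
    list(gy * (g[1L] / n))
  })
}

ag_sum <- function(x) {
  ag_node(matrix(sum(x$val), 1L, 1L), list(x), function(g) {
    list(matrix(g[1L], nrow(x$val), ncol(x$val)))
  })
}

# Fused LSTM over a whole sequence with hand-written backpropagation
# through time. x: (n_steps * batch) x input rows in step-major order (step 1
# rows first). wx: input x 4*hidden, wh: hidden x 4*hidden, bi/bh: 1 x
# 4*hidden (both biases are kept as separate parameters; they enter the
# forward as their sum and share the same gradient). Gate order i, f, g, o.
# Returns the (n_steps * batch) x hidden matrix of hidden states.
ag_lstm_seq <- function(x, wx, wh, bi, bh, n_steps) {
  hdim <- nrow(wh$val)
  b <- nrow(x$val) %/% n_steps
  zx <- .addrow(x$val %*% wx$val, as.vector(bi$val) + as.vector(bh$val))
  i1 <- 1:hdim; i2 <- (hdim + 1L):(2L * hdim)
  i3 <- (2L * hdim + 1L):(3L * hdim); i4 <- (3L * hdim + 1L):(4L * hdim)
  n <- n_steps * b
  gi <- matrix(0, n, hdim); gf <- matrix(0, n, hdim)
  gg <- matrix(0, n, hdim); go <- matrix(0, n, hdim)
  tc <- matrix(0, n, hdim); cprev <- matrix(0, n, hdim)
  out <- matrix(0, n, hdim)
  h <- matrix(0, b, hdim)
  cc <- matrix(0, b, hdim)
  for (t in seq_len(n_steps)) {
    rows <- ((t - 1L) * b + 1L):(t * b)
    z <- zx[rows, , drop = FALSE] + h %*% wh$val
    i <- 1 / (1 + exp(-z[, i1, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, i2, drop = FALSE]))
    g <- tanh(z[, i3, drop = FALSE])
    o <- 1 / (1 + exp(-z[, i4, drop = FALSE]))
    cprev[rows, ] <- cc
    cc <- f * cc + i * g
    tcc <- tanh(cc)
    h <- o * tcc
    gi[rows, ] <- i; gf[rows, ] <- f; gg[rows, ] <- g; go[rows, ] <- o
    tc[rows, ] <- tcc; out[rows, ] <- h
  }
  ag_node(out, list(x, wx, wh, bi, bh), function(gout) {
    dzx <- matrix(0, n, 4L * hdim)
    dwh <- matrix(0, hdim, 4L * hdim)
    dh <- matrix(0, b, hdim)
    dc <- matrix(0, b, hdim)
    wh_t <- t(wh$val)
    for (t in rev(seq_len(n_steps))) {
      rows <- ((t - 1L) * b + 1L):(t * b)
      i <- gi[rows, , drop = FALSE]; f <- gf[rows, , drop = FALSE]
      g <- gg[rows, , drop = FALSE]; o <- go[rows, , drop = FALSE]
      tcc <- tc[rows, , drop = FALSE]
      dht <- gout[rows, , drop = FALSE] + dh
      dc <- dc + dht * o * (1 - tcc^2)
      dz <- cbind(dc * g * i * (1 - i),
                  dc * cprev[rows, , drop = FALSE] * f * (1 - f),
                  dc * i * (1 - g^2),
                  dht * tcc * o * (1 - o))
      dzx[rows, ] <- dz
      hprev <- if (t > 1L) out[rows - b, , drop = FALSE] else matrix(0, b, hdim)
      dwh <- dwh + crossprod(hprev, dz)
      dh <- dz %*% wh_t
      dc <- dc * f
    }
    db <- matrix(colSums(dzx), 1L)
    list(dzx %*% t(wx$val), crossprod(x$val, dzx), dwh, db, db)
  })
}

# Fused GRU sequence (gate order r, z, n; the candidate gate applies the
# reset gate to the recurrent term including its bias, so bi and bh are not
# interchangeable). Layout as ag_lstm_seq.
ag_gru_seq <- function(x, wx, wh, bi, bh, n_steps) {
  hdim <- nrow(wh$val)
  b <- nrow(x$val) %/% n_steps
  zx <- .addrow(x$val %*% wx$val, as.vector(bi$val))
  i1 <- 1:hdim; i2 <- (hdim + 1L):(2L * hdim); i3 <- (2L * hdim + 1L):(3L * hdim)
  n <- n_steps * b
  gr <- matrix(0, n, hdim); gu <- matrix(0, n, hdim)
  gn <- matrix(0, n, hdim); zh3 <- matrix(0, n, hdim)
  out <- matrix(0, n, hdim)
  h <- matrix(0, b, hdim)
  bhv <- as.vector(bh$val)
  for (t in seq_len(n_steps)) {
    rows <- ((t - 1L) * b + 1L):(t * b)
    zh <- .addrow(h %*% wh$val, bhv)
    r <- 1 / (1 + exp(-(zx[rows, i1, drop = FALSE] + zh[, i1, drop = FALSE])))
    u <- 1 / (1 + exp(-(zx[rows, i2, drop = FALSE] + zh[, i2, drop = FALSE])))
    nn <- tanh(zx[rows, i3, drop = FALSE] + r * zh[, i3, drop = FALSE])
    h <- (1 - u) * nn + u * h
    gr[rows, ] <- r; gu[rows, ] <- u; gn[rows, ] <- nn
    zh3[rows, ] <- zh[, i3, drop = FALSE]
    out[rows, ] <- h
  }
  ag_node(out, list(x, wx, wh, bi, bh), function(gout) {
    dzx <- matrix(0, n, 3L * hdim)
    dwh <- matrix(0, hdim, 3L * hdim)
    dbh <- numeric(3L * hdim)
    dh <- matrix(0, b, hdim)
    wh_t <- t(wh$val)
    for (t in rev(seq_len(n_steps))) {
      rows <- ((t - 1L) * b + 1L):(t * b)
      r <- gr[rows, , drop = FALSE]; u <- gu[rows, , drop = FALSE]
      nn <- gn[rows, , drop = FALSE]
      hprev <- if (t > 1L) out[rows - b, , drop = FALSE] else matrix(0, b, hdim)
      dht <- gout[rows, , drop = FALSE] + dh
      du <- dht * (hprev - nn) * u * (1 - u)
      dn <- dht * (1 - u)
      dzx3 <- dn * (1 - nn^2)
      dr <- dzx3 * zh3[rows, , drop = FALSE] * r * (1 - r)
      dzh <- cbind(dr, du, dzx3 * r)
      dzx[rows, ] <- cbind(dr, du, dzx3)
      dwh <- dwh + crossprod(hprev, dzh)
      dbh <- dbh + colSums(dzh)
      dh <- dht * u + dzh %*% wh_t
    }
    list(dzx %*% t(wx$val), crossprod(x$val, dzx), dwh,
         matrix(colSums(dzx), 1L), matrix(dbh, 1L))
  })
}

## ---- Adam optimiser --------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p$val * 0),
    v = lapply(params, function(p) p$val * 0),
    t = 0L,
    beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
}

adam_step <- function(opt, params, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1
  b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (j in seq_along(params)) {
    p <- params[[j]]
    if (is.null(p$grad)) next
    opt$m[[j]] <- b1 * opt$m[[j]] + (1 - b1) * p$grad
    opt$v[[j]] <- b2 * opt$v[[j]] + (1 - b2) * p$grad^2
    mhat <- opt$m[[j]] / c1
    vhat <- opt$v[[j]] / c2
    p$val <- p$val - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}
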