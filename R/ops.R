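# Differentiable operations on the autograd tape.
#
# Feature-map layout throughout: (channels, time, n_sequences), column-major.
# Vector/feature layout for dense layers: (features, batch).

op_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

op_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ag_node(tape, av * bv, list(a, b),
          function(g) list(g * bv, g * av))
}

op_scale <- function(tape, a, s) {
  ag_node(tape, a$value * s, list(a), function(g) list(g * s))
}

op_elu <- function(tape, x, alpha = 1) {
  y <- cpp_elu_fwd(x$value, alpha)
  ag_node(tape, y, list(x), function(g) list(cpp_elu_bwd(y, g, alpha)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

op_relu <- function(tape, x) {
  xv <- x$value
  y <- pmax(xv, 0)
  dim(y) <- dim(xv)
  ag_node(tape, y, list(x), function(g) list(g * (xv > 0)))
}

op_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- cpp_dropout_mask(length(x$value), p)
  dim(mask) <- dim(x$value)
  ag_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

# Fused first two encoder stages: temporal convolution (single input
# plane, same padding) -> batch norm -> depthwise electrode convolution.
# x is the raw (T, C*B) data (no gradient needed); per-sequence
# intermediates are recomputed in cache rather than materialized.
op_front <- function(tape, x, W1, gamma, beta, Wd, state, training) {
  dx <- dim(x)
  T_ <- dx[1]
  F1 <- dim(W1$value)[1]
  K <- dim(W1$value)[3]
  C <- dim(Wd$value)[1]
  D <- dim(Wd$value)[2]
  B <- dx[2] %/% C
  pl <- same_pad(K)[1]
  fw <- cpp_front_fwd(x, T_, C, B, W1$value, F1, K, pl,
                      gamma$value, beta$value, Wd$value, D, state$eps,
                      !training, state$running_mean, state$running_var)
  if (training) bn_track(state, fw$mu, fw$var, T_ * C * B)
  W1v <- W1$value; gv <- gamma$value; bv <- beta$value; Wdv <- Wd$value
  ag_node(tape, fw$z, list(W1, gamma, beta, Wd), function(g) {
    bw <- cpp_front_bwd(x, g, T_, C, B, W1v, F1, K, pl, gv, Wdv, D,
                        fw$mu, fw$invsd)
    A <- fw$invsd * gv
    shift <- bv - fw$mu * A
    gzsum <- matrix(bw$gzsum, D, F1)
    gWd <- sweep(bw$gWd_partial, 3, A, "*") +
      array(rep(as.vector(sweep(gzsum, 2, shift, "*")), each = C),
            c(C, D, F1))
    list(bw$gW1, bw$ggamma, bw$gbeta, gWd)
  })
}

# 1-D convolution along time; W node (outC, inC, K); optional bias node.
op_conv1d <- function(tape, x, W, b = NULL, dilation = 1L,
                      pad = c(0L, 0L)) {
  dx <- dim(x$value)
  inC <- dx[1]; T_ <- dx[2]; N <- dx[3]
  dw <- dim(W$value)
  outC <- dw[1]; K <- dw[3]
  stopifnot(dw[2] == inC)
  y <- cpp_conv1d_fwd(x$value, inC, T_, N, W$value, outC, K,
                      as.integer(dilation), as.integer(pad[1]),
                      as.integer(pad[2]))
  parents <- list(x, W)
  if (!is.null(b)) {
    y <- y + as.vector(b$value)  # outC is the first dim: recycles per channel
    parents <- c(parents, list(b))
  }
  xv <- x$value; Wv <- W$value
  ag_node(tape, y, parents, function(g) {
    bw <- cpp_conv1d_bwd(xv, g, inC, T_, N, Wv, outC, K,
                         as.integer(dilation), as.integer(pad[1]),
                         as.integer(pad[2]))
    out <- list(bw$gx, bw$gW)
    if (!is.null(b)) out <- c(out, list(rowSums(matrix(g, nrow = outC))))
    out
  })
}

same_pad <- function(K, dilation = 1L) {
  span <- (K - 1L) * dilation
  pl <- span %/% 2L
  c(pl, span - pl)
}

causal_pad <- function(K, dilation = 1L) c((K - 1L) * dilation, 0L)

# Depthwise electrode convolution: x (F1, T, C*B) with electrode-fastest
# sequence order; W (C, D, F1); output (F1*D, T, B).
op_dwconv <- function(tape, x, W, C, B) {
  dx <- dim(x$value)
  F1 <- dx[1]; T_ <- dx[2]
  stopifnot(dx[3] == C * B)
  D <- dim(W$value)[2]
  y <- cpp_dwconv_fwd(x$value, F1, T_, C, B, W$value, D)
  xv <- x$value; Wv <- W$value
  ag_node(tape, y, list(x, W), function(g) {
    bw <- cpp_dwconv_bwd(xv, g, F1, T_, C, B, Wv, D)
    list(bw$gx, bw$gW)
  })
}

# Update a batch-norm state with one batch's statistics: an exponential
# moving average during ordinary training, or exact accumulation during a
# calibration sweep (state$calib set by calibrate_bn()).
bn_track <- function(state, mu, v_batch, m) {
  if (isTRUE(state$calib)) {
    state$acc_n <- state$acc_n + m
    state$acc_s1 <- state$acc_s1 + m * mu
    state$acc_s2 <- state$acc_s2 + m * (v_batch + mu^2)
  } else {
    mom <- state$momentum
    state$running_mean <- (1 - mom) * state$running_mean + mom * mu
    state$running_var <- (1 - mom) * state$running_var + mom * v_batch
  }
  invisible(NULL)
}

# Batch normalization per channel (first dim). `state` is an environment
# with running_mean, running_var, momentum, eps; updated in training mode.
op_bn <- function(tape, x, gamma, beta, state, training) {
  C <- dim(x$value)[1]
  if (training) {
    fw <- cpp_bn_fwd(x$value, C, gamma$value, beta$value, state$eps)
    v_batch <- 1 / fw$invsd^2 - state$eps
    bn_track(state, fw$mu, v_batch, length(x$value) / C)
    xv <- x$value
    ag_node(tape, fw$y, list(x, gamma, beta), function(g) {
      bw <- cpp_bn_bwd(xv, g, C, fw$mu, fw$invsd, gamma$value)
      list(bw$gx, bw$ggamma, bw$gbeta)
    })
  } else {
    mu <- state$running_mean
    invsd <- 1 / sqrt(state$running_var + state$eps)
    y <- cpp_bn_apply(x$value, C, mu, invsd, gamma$value, beta$value)
    xv <- x$value
    ag_node(tape, y, list(x, gamma, beta), function(g) {
      scale <- invsd * gamma$value
      xhat <- (xv - mu) * invsd  # per-channel recycling over first dim
      gm <- matrix(g, nrow = C)
      list(g * scale, rowSums(gm * matrix(xhat, nrow = C)), rowSums(gm))
    })
  }
}

# Average pooling along time with kernel k (floor semantics: trailing
# remainder samples are dropped, matching pooled length floor(T/k)).
op_avgpool_time <- function(tape, x, k) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  T2 <- T_ %/% k
  stopifnot(T2 >= 1)
  xv <- x$value
  xm <- if (T2 * k == T_) xv else xv[, seq_len(T2 * k), , drop = FALSE]
  dim(xm) <- c(C, k, T2, N)
  y <- xm[, 1, , , drop = FALSE] / k
  if (k > 1) for (i in 2:k) y <- y + xm[, i, , , drop = FALSE] / k
  dim(y) <- c(C, T2, N)
  ag_node(tape, y, list(x), function(g) {
    ge <- array(0, c(C, k, T2, N))
    gk <- g / k
    for (i in seq_len(k)) ge[, i, , ] <- gk
    dim(ge) <- c(C, k * T2, N)
    if (T2 * k == T_) return(list(ge))
    gx <- array(0, c(C, T_, N))
    gx[, seq_len(T2 * k), ] <- ge
    list(gx)
  })
}

# Global (adaptive, output length 1) average pooling over time: (C,T,N)->(C,N).
op_global_avg_time <- function(tape, x) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  y <- colMeans(aperm(x$value, c(2, 1, 3)))
  dim(y) <- c(C, N)
  ag_node(tape, y, list(x), function(g) {
    gx <- aperm(array(as.vector(g / T_), c(C, N, T_)), c(1, 3, 2))
    list(gx)
  })
}

op_global_max_time <- function(tape, x) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  xv <- x$value
  cur <- matrix(xv[, 1, ], C, N)
  idx <- matrix(1L, C, N)
  if (T_ > 1) {
    for (t in 2:T_) {
      xt <- matrix(xv[, t, ], C, N)
      upd <- xt > cur
      cur[upd] <- xt[upd]
      idx[upd] <- t
    }
  }
  ag_node(tape, cur, list(x), function(g) {
    gx <- array(0, c(C, T_, N))
    flat <- as.vector(row(idx)) + C * (as.vector(idx) - 1L) +
      (C * T_) * (as.vector(col(idx)) - 1L)
    gx[flat] <- gx[flat] + as.vector(g)
    list(gx)
  })
}

# Channel-wise broadcast multiply: x (C,T,N) * w (C,N).
op_mul_bcast_channel <- function(tape, x, w) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  we <- aperm(array(as.vector(w$value), c(C, N, T_)), c(1, 3, 2))
  xv <- x$value
  ag_node(tape, xv * we, list(x, w), function(g) {
    gw <- colSums(aperm(g * xv, c(2, 1, 3)))
    dim(gw) <- c(C, N)
    list(g * we, gw)
  })
}

# Time-wise broadcast multiply: x (C,T,N) * s (1,T,N).
op_mul_bcast_time <- function(tape, x, s) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  se <- array(rep(as.vector(s$value), each = C), c(C, T_, N))
  xv <- x$value
  ag_node(tape, xv * se, list(x, s), function(g) {
    gs <- colSums(matrix(g * xv, nrow = C))
    dim(gs) <- c(1, T_, N)
    list(g * se, gs)
  })
}

# Mean and max across channels -> (1, T, N) each (CBAM spatial descriptors).
op_channel_mean <- function(tape, x) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  y <- colMeans(matrix(x$value, nrow = C))
  dim(y) <- c(1, T_, N)
  ag_node(tape, y, list(x), function(g) {
    gx <- array(rep(as.vector(g) / C, each = C), c(C, T_, N))
    list(gx)
  })
}

op_channel_max <- function(tape, x) {
  dx <- dim(x$value)
  C <- dx[1]; T_ <- dx[2]; N <- dx[3]
  xm <- matrix(x$value, nrow = C)
  idx <- max.col(t(xm), ties.method = "first")
  y <- xm[cbind(idx, seq_along(idx))]
  dim(y) <- c(1, T_, N)
  ag_node(tape, y, list(x), function(g) {
    gx <- array(0, c(C, T_, N))
    flat <- idx + C * (seq_along(idx) - 1L)
    gx[flat] <- gx[flat] + as.vector(g)
    list(gx)
  })
}

# Stack two (1,T,N) maps into a 2-channel map (2,T,N).
op_stack2 <- function(tape, a, b) {
  dx <- dim(a$value)
  T_ <- dx[2]; N <- dx[3]
  y <- array(0, c(2, T_, N))
  y[1, , ] <- a$value
  y[2, , ] <- b$value
  ag_node(tape, y, list(a, b), function(g) {
    list(array(g[1, , ], c(1, T_, N)), array(g[2, , ], c(1, T_, N)))
  })
}

# Dense layer in (features, batch) layout: y = W %*% x + b.
op_linear_cols <- function(tape, x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  y <- Wv %*% xv
  parents <- list(x, W)
  if (!is.null(b)) {
    y <- y + b$value  # rows = output features: recycles per feature
    parents <- c(parents, list(b))
  }
  ag_node(tape, y, parents, function(g) {
    out <- list(crossprod(Wv, g), tcrossprod(g, xv))
    if (!is.null(b)) out <- c(out, list(rowSums(g)))
    out
  })
}

# Contiguous time-window slice: (C, Tc, N) -> (C, Tw, N) starting at `start`.
op_window <- function(tape, x, start, Tw) {
  dx <- dim(x$value)
  C <- dx[1]; Tc <- dx[2]; N <- dx[3]
  sel <- start:(start + Tw - 1L)
  y <- x$value[, sel, , drop = FALSE]
  ag_node(tape, y, list(x), function(g) {
    gx <- array(0, c(C, Tc, N))
    gx[, sel, ] <- g
    list(gx)
  })
}

# Concatenate along the sequence (third) dimension.
op_concat_seq <- function(tape, nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  C <- dims[[1]][1]; T_ <- dims[[1]][2]
  Ns <- vapply(dims, function(d) d[3], numeric(1))
  y <- array(unlist(lapply(nodes, function(n) n$value), use.names = FALSE),
             c(C, T_, sum(Ns)))
  ends <- cumsum(Ns)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(tape, y, nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      array(g[, , starts[i]:ends[i]], c(C, T_, Ns[i]))
    })
  })
}

# Concatenate feature-column matrices (features, B) along the feature dim.
op_concat_features <- function(tape, nodes) {
  Fs <- vapply(nodes, function(n) nrow(n$value), numeric(1))
  y <- do.call(rbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(Fs)
  starts <- c(1, head(ends, -1) + 1)
  ag_node(tape, y, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# (F, n*B) with instance order b + B*(w-1)  ->  (F*n, B), window-major rows.
op_fold_windows <- function(tape, x, n, B) {
  F_ <- dim(x$value)[1]
  x3 <- array(x$value, c(F_, B, n))
  y <- matrix(aperm(x3, c(1, 3, 2)), F_ * n, B)
  ag_node(tape, y, list(x), function(g) {
    g3 <- aperm(array(g, c(F_, n, B)), c(1, 3, 2))
    gm <- matrix(g3, F_, B * n)
    list(gm)
  })
}

# Fast-normalized weighted fusion: O = sum_i relu(w_i) I_i / (eps + sum relu).
op_fuse <- function(tape, inputs, w, eps) {
  wv <- as.vector(w$value)
  u <- pmax(wv, 0)
  S <- eps + sum(u)
  coef <- u / S
  y <- inputs[[1]]$value * coef[1]
  for (i in seq_along(inputs)[-1]) y <- y + inputs[[i]]$value * coef[i]
  vals <- lapply(inputs, function(n) n$value)
  ag_node(tape, y, c(inputs, list(w)), function(g) {
    gi <- lapply(seq_along(inputs), function(i) g * coef[i])
    gu <- vapply(seq_along(inputs), function(i) {
      sum(g * (vals[[i]] - y)) / S
    }, numeric(1))
    gw <- gu * (wv > 0)
    c(gi, list(gw))
  })
}

# Linear resampling along time to Tout points (endpoints aligned).
resample_matrix <- function(Tin, Tout) {
  M <- matrix(0, Tin, Tout)
  if (Tout == 1) {
    M[, 1] <- 1 / Tin
    return(M)
  }
  pos <- (seq_len(Tout) - 1) * (Tin - 1) / (Tout - 1) + 1
  lo <- pmin(floor(pos), Tin - 1)
  frac <- pos - lo
  for (j in seq_len(Tout)) {
    if (Tin == 1) {
      M[1, j] <- 1
    } else {
      M[lo[j], j] <- M[lo[j], j] + 1 - frac[j]
      M[lo[j] + 1, j] <- M[lo[j] + 1, j] + frac[j]
    }
  }
  M
}

op_resample_time <- function(tape, x, Tout) {
  dx <- dim(x$value)
  C <- dx[1]; Tin <- dx[2]; N <- dx[3]
  if (Tin == Tout) return(x)
  M <- resample_matrix(Tin, Tout)
  xp <- matrix(aperm(x$value, c(1, 3, 2)), C * N, Tin)
  y <- aperm(array(xp %*% M, c(C, N, Tout)), c(1, 3, 2))
  ag_node(tape, y, list(x), function(g) {
    gp <- matrix(aperm(g, c(1, 3, 2)), C * N, Tout)
    gx <- aperm(array(tcrossprod(gp, M), c(C, N, Tin)), c(1, 3, 2))
    list(gx)
  })
}

# Softmax cross-entropy over logit columns (n_classes, B); labels 0-based.
op_softmax_ce <- function(tape, logits, labels) {
  lv <- logits$value
  B <- ncol(lv)
  m <- apply(lv, 2, max)
  e <- exp(sweep(lv, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  picked <- probs[cbind(labels + 1L, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  nd <- ag_node(tape, loss, list(logits), function(g) {
    gl <- probs
    gl[cbind(labels + 1L, seq_len(B))] <-
      gl[cbind(labels + 1L, seq_len(B))] - 1
    list(gl * (g / B))
  })
  nd$probs <- probs
  nd
}

softmax_cols <- function(lv) {
  m <- apply(lv, 2, max)
  e <- exp(sweep(lv, 2, m))
  sweep(e, 2, colSums(e), "/")
}
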