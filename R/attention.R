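# Sliding-window multi-head self-attention branch.
#
# Each encoder band series z (T_c x d) is cut into n overlapping windows of
# length T_w = T_c - n + 1; every window is processed by multi-head
# scaled-dot-product self-attention (with residual connection and dropout)
# and the temporal convolution block, then summarized by adaptive average
# pooling; window summaries are concatenated into the branch feature vector.

#' Attention block configuration
#'
#' @param n_heads Number of attention heads.
#' @param head_dim Per-head projection width d_k.
#' @param dropout Dropout probability applied to the attention output.
#' @param enabled If `FALSE` the block is an identity map (ablation).
#' @return Object of class `attention_config`.
#' @export
attention_config <- function(n_heads = 2L, head_dim = 32L, dropout = 0.12,
                             enabled = TRUE) {
  stopifnot(n_heads >= 1, head_dim >= 1, dropout >= 0, dropout < 1)
  structure(list(n_heads = as.integer(n_heads),
                 head_dim = as.integer(head_dim),
                 dropout = dropout, enabled = isTRUE(enabled)),
            class = "attention_config")
}

#' Cut a band series into overlapping sliding windows
#'
#' Produces `n` windows of length `T_c - n + 1` with consecutive start
#' offsets, so window starts cover offsets `0 .. n-1` and window length
#' plus `n - 1` equals `T_c`.
#'
#' @param z Numeric matrix (T_c x d), one band series.
#' @param n Number of windows; must satisfy `1 <= n < T_c`.
#' @return Object of class `window_set`: list of `n` matrices
#'   (T_w x d) with attributes `n`, `window_length` and `source_length`.
#' @export
make_windows <- function(z, n) {
  if (!is.matrix(z)) stop("z must be a matrix (time x features)")
  Tc <- nrow(z)
  n <- as.integer(n)
  if (n < 1 || n >= Tc) stop("window count must satisfy 1 <= n < T_c")
  Tw <- Tc - n + 1L
  ws <- lapply(seq_len(n), function(w) z[w:(w + Tw - 1L), , drop = FALSE])
  structure(ws, n = n, window_length = Tw, source_length = Tc,
            class = "window_set")
}

#' Scaled dot-product attention scores
#'
#' Row-stochastic score matrix `softmax_b(q_a . k_b / sqrt(d_k))`; every row
#' sums to 1 and all entries lie in (0, 1).
#'
#' @param q Query matrix (T x d_k).
#' @param k Key matrix (T x d_k).
#' @return T x T score matrix.
#' @export
attention_scores <- function(q, k) {
  if (!is.matrix(q) || !is.matrix(k)) stop("q and k must be matrices")
  dk <- ncol(q)
  if (dk == 0) stop("d_k must be positive")
  if (ncol(k) != dk) stop("q and k must share d_k")
  a <- tcrossprod(q, k) / sqrt(dk)
  a <- a - max(a)  # bounded above: exp cannot overflow
  e <- exp(a)
  e / rowSums(e)
}

#' Apply attention scores to value rows
#'
#' Each output row is the score-weighted convex combination of value rows
#' (`z_a = sum_b s[a,b] v_b`).
#'
#' @param s Row-stochastic score matrix (T x T).
#' @param v Value matrix (T x d_k).
#' @return T x d_k matrix.
#' @export
attention_apply <- function(s, v) {
  if (!is.matrix(s) || !is.matrix(v)) stop("s and v must be matrices")
  if (ncol(s) != nrow(v) || nrow(s) != ncol(s)) {
    stop("s must be T x T and v T x d_k")
  }
  if (max(abs(rowSums(s) - 1)) > 1e-6) {
    stop("s must be row-stochastic")
  }
  s %*% v
}

# Multi-head self-attention over N sequences as one composite tape op.
# x: (d, Tw, N). Wq/Wk/Wv: lists of H nodes (d x dk); Wo: node (H*dk x d).
# Intermediates are recomputed during the backward sweep to save memory.
op_mha <- function(tape, x, Wq, Wk, Wv, Wo) {
  xv <- x$value
  d <- dim(xv)[1]; Tw <- dim(xv)[2]; N <- dim(xv)[3]
  H <- length(Wq)
  dk <- ncol(Wq[[1]]$value)
  # one gemm projects all heads' queries/keys/values for all sequences
  Wcat <- cbind(do.call(cbind, lapply(Wq, function(n) n$value)),
                do.call(cbind, lapply(Wk, function(n) n$value)),
                do.call(cbind, lapply(Wv, function(n) n$value)))
  Wov <- Wo$value
  qc <- function(h) ((h - 1L) * dk + 1L):(h * dk)
  kc <- function(h) H * dk + qc(h)
  vc <- function(h) 2L * H * dk + qc(h)
  E <- t(matrix(xv, d, Tw * N))
  QKV <- E %*% Wcat
  conc <- matrix(0, Tw * N, H * dk)
  for (b in seq_len(N)) {
    rows <- ((b - 1L) * Tw + 1L):(b * Tw)
    for (h in seq_len(H)) {
      s <- attention_scores(QKV[rows, qc(h), drop = FALSE],
                            QKV[rows, kc(h), drop = FALSE])
      conc[rows, qc(h)] <- s %*% QKV[rows, vc(h), drop = FALSE]
    }
  }
  y <- array(t(conc %*% Wov), c(d, Tw, N))
  parents <- c(list(x), Wq, Wk, Wv, list(Wo))
  ag_node(tape, y, parents, function(g) {
    dY <- t(matrix(g, d, Tw * N))
    QKV <- E %*% Wcat  # recomputed; per-head scores rebuilt per sequence
    dQKV <- matrix(0, Tw * N, 3L * H * dk)
    conc <- matrix(0, Tw * N, H * dk)
    dConc <- tcrossprod(dY, Wov)
    sq <- sqrt(dk)
    for (b in seq_len(N)) {
      rows <- ((b - 1L) * Tw + 1L):(b * Tw)
      for (h in seq_len(H)) {
        Q <- QKV[rows, qc(h), drop = FALSE]
        K <- QKV[rows, kc(h), drop = FALSE]
        V <- QKV[rows, vc(h), drop = FALSE]
        s <- attention_scores(Q, K)
        conc[rows, qc(h)] <- s %*% V
        do_h <- dConc[rows, qc(h), drop = FALSE]
        ds <- tcrossprod(do_h, V)
        dA <- s * (ds - rowSums(ds * s))
        dQKV[rows, qc(h)] <- (dA %*% K) / sq
        dQKV[rows, kc(h)] <- crossprod(dA, Q) / sq
        dQKV[rows, vc(h)] <- crossprod(s, do_h)
      }
    }
    gWo <- crossprod(conc, dY)
    gWcat <- crossprod(E, dQKV)
    dE <- tcrossprod(dQKV, Wcat)
    gx <- array(t(dE), c(d, Tw, N))
    gWq <- lapply(seq_len(H), function(h) gWcat[, qc(h), drop = FALSE])
    gWk <- lapply(seq_len(H), function(h) gWcat[, kc(h), drop = FALSE])
    gWv <- lapply(seq_len(H), function(h) gWcat[, vc(h), drop = FALSE])
    c(list(gx), gWq, gWk, gWv, list(gWo))
  })
}

mha_params <- function(prefix, d, cfg, std) {
  P <- list()
  for (h in seq_len(cfg$n_heads)) {
    for (nm in c("Wq", "Wk", "Wv")) {
      key <- paste0(prefix, ".at.", nm, ".", h)
      P[[key]] <- new_param(param_normal(c(d, cfg$head_dim), std), key)
    }
  }
  key <- paste0(prefix, ".at.Wo")
  P[[key]] <- new_param(
    param_normal(c(cfg$n_heads * cfg$head_dim, d), std), key)
  P
}

mha_tape <- function(tape, P, prefix, x) {
  pick <- function(nm) {
    hs <- grep(paste0("^", prefix, "\\.at\\.", nm, "\\."), names(P),
               value = TRUE)
    hs <- hs[order(as.integer(sub(".*\\.", "", hs)))]
    lapply(hs, function(k) ag_leaf(tape, P[[k]]))
  }
  op_mha(tape, x, pick("Wq"), pick("Wk"), pick("Wv"),
         ag_leaf(tape, P[[paste0(prefix, ".at.Wo")]]))
}

#' Multi-head self-attention over one sequence
#'
#' Runs per-head scaled dot-product attention (queries, keys and values are
#' linear projections of the input rows), concatenates ("splices") the head
#' outputs and projects back to the input width.
#'
#' @param e Numeric matrix (T x d), one windowed band series.
#' @param n_heads,head_dim Head count and per-head width d_k.
#' @param weights Optional list with `Wq`, `Wk`, `Wv` (lists of d x d_k
#'   matrices, one per head) and `Wo` (n_heads*d_k x d).
#' @param std,seed Initialization used when `weights` is `NULL`.
#' @return T x d matrix of attention output (before residual addition).
#' @export
multihead_attention <- function(e, n_heads = 2L, head_dim = 32L,
                                weights = NULL, std = 0.01, seed = 1L) {
  if (!is.matrix(e)) stop("e must be a matrix (time x features)")
  d <- ncol(e)
  cfg <- attention_config(n_heads = n_heads, head_dim = head_dim)
  P <- if (is.null(weights)) {
    with_seeded_params(seed, function() mha_params("br", d, cfg, std))
  } else {
    P <- list()
    for (h in seq_len(n_heads)) {
      P[[paste0("br.at.Wq.", h)]] <- new_param(weights$Wq[[h]])
      P[[paste0("br.at.Wk.", h)]] <- new_param(weights$Wk[[h]])
      P[[paste0("br.at.Wv.", h)]] <- new_param(weights$Wv[[h]])
    }
    P[["br.at.Wo"]] <- new_param(weights$Wo)
    P
  }
  tape <- ag_tape()
  x <- ag_const(tape, array(t(e), c(d, nrow(e), 1)))
  out <- mha_tape(tape, P, "br", x)
  t(matrix(out$value, d, nrow(e)))
}

branch_params <- function(prefix, d, at_cfg, tc_cfg, std) {
  P <- list()
  if (at_cfg$enabled) P <- c(P, mha_params(prefix, d, at_cfg, std))
  if (tc_cfg$enabled) P <- c(P, tcn_params(prefix, d, tc_cfg, std))
  P
}

branch_states <- function(prefix, tc_cfg) {
  S <- list()
  if (tc_cfg$enabled) {
    for (l in seq_len(tc_cfg$n_blocks)) {
      for (j in 1:2) {
        S[[paste0(prefix, ".tc.b", l, ".bn", j)]] <- bn_state(tc_cfg$filters)
      }
    }
  }
  S
}

# One branch: windows -> attention (+residual, dropout) -> TCN -> pooled
# summaries folded to a (filters * n_windows, B) feature block.
branch_forward_tape <- function(tape, P, S, z, n_windows, at_cfg, tc_cfg,
                                training, prefix) {
  Tc <- dim(z$value)[2]
  B <- dim(z$value)[3]
  n <- as.integer(n_windows)
  if (n < 1 || n >= Tc) stop("window count must satisfy 1 <= n < T_c")
  Tw <- Tc - n + 1L
  outs <- vector("list", n)
  for (w in seq_len(n)) {
    win <- op_window(tape, z, w, Tw)
    if (at_cfg$enabled) {
      at <- mha_tape(tape, P, prefix, win)
      at <- op_dropout(tape, at, at_cfg$dropout, training)
      outs[[w]] <- op_add(tape, win, at)
    } else {
      outs[[w]] <- win
    }
  }
  h <- if (n > 1) op_concat_seq(tape, outs) else outs[[1]]
  if (tc_cfg$enabled) {
    h <- tcn_forward_tape(tape, P, S, h, tc_cfg, training, prefix)
  }
  pooled <- op_global_avg_time(tape, h)
  op_fold_windows(tape, pooled, n, B)
}

#' Process one band series through a full attention/TCN branch
#'
#' Splits `z` into `n_windows` sliding windows, applies multi-head
#' self-attention with a residual connection, the temporal convolution
#' block, and adaptive average pooling per window, then concatenates the
#' per-window summaries.
#'
#' @param z Numeric matrix (T_c x d).
#' @param n_windows Number of sliding windows.
#' @param at_cfg An [attention_config()].
#' @param tc_cfg A [tcn_config()].
#' @param std,seed Initialization of the branch weights.
#' @return Numeric vector of length `n_windows * tc_cfg$filters`.
#' @export
branch_forward <- function(z, n_windows = 5L, at_cfg = attention_config(),
                           tc_cfg = tcn_config(), std = 0.01, seed = 1L) {
  if (!is.matrix(z)) stop("z must be a matrix (time x features)")
  d <- ncol(z)
  P <- with_seeded_params(seed, function() {
    branch_params("br", d, at_cfg, tc_cfg, std)
  })
  S <- branch_states("br", tc_cfg)
  tape <- ag_tape()
  zn <- ag_const(tape, array(t(z), c(d, nrow(z), 1)))
  out <- branch_forward_tape(tape, P, S, zn, n_windows, at_cfg, tc_cfg,
                             training = FALSE, prefix = "br")
  as.vector(out$value)
}
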